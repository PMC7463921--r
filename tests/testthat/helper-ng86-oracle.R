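# Independent per-codon counting oracle for the NG86 estimator, written
# against the estimator before the package implementation and kept on a
# deliberately different code path: the genetic code is built from the
# classic 64-character translation string indexed in TCAG order, site
# fractions are accumulated by explicit base loops, and substitution
# pathways are enumerated as explicit permutations.

oracle_code <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  codons <- as.vector(vapply(b, function(p1)
    vapply(b, function(p2)
      vapply(b, function(p3) paste0(p1, p2, p3), ""), character(4)), matrix("", 4, 4)))
  # codons enumerate p3 fastest given the nesting above; rebuild explicitly
  codons <- character(64); k <- 0
  for (p1 in b) for (p2 in b) for (p3 in b) { k <- k + 1; codons[k] <- paste0(p1, p2, p3) }
  stats::setNames(aa, codons)
})

oracle_syn_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  aa <- oracle_code[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nb in bases) {
      if (nb == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nb
      if (oracle_code[[mut]] == "*") next
      valid <- valid + 1
      if (oracle_code[[mut]] == aa) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (rest in oracle_perms(v[-i]))
    out <- c(out, list(c(v[i], rest)))
  out
}

oracle_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  paths <- oracle_perms(pos)
  acc <- NULL
  for (p in paths) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (q in p) {
      nxt <- cur
      substr(nxt, q, q) <- substr(c2, q, q)
      if (oracle_code[[nxt]] == "*") { ok <- FALSE; break }
      if (oracle_code[[nxt]] == oracle_code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc <- rbind(acc, c(sd, nd))
  }
  if (is.null(acc)) {     # all pathways blocked by stops: count them anyway
    for (p in paths) {
      cur <- c1; sd <- 0; nd <- 0
      for (q in p) {
        nxt <- cur
        substr(nxt, q, q) <- substr(c2, q, q)
        same <- oracle_code[[nxt]] != "*" && oracle_code[[cur]] != "*" &&
          oracle_code[[nxt]] == oracle_code[[cur]]
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      acc <- rbind(acc, c(sd, nd))
    }
  }
  colMeans(acc)
}

oracle_ng86 <- function(seq_a, seq_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(toupper(seq_a)); cb <- split3(toupper(seq_b))
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[ok]; cb <- cb[ok]
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) +
        sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) oracle_diffs(ca[i], cb[i]), numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(Sd / S), ka = jc(Nd / N), S = S, N = N, Sd = Sd, Nd = Nd)
}
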