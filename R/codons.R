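# Standard genetic code and per-codon site accounting used by the NG86
# Ka/Ks estimator and the codon-pair simulator.

GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

BASES <- c("T", "C", "A", "G")

translate_codon <- function(codon) unname(GENETIC_CODE_STD[codon])

is_stop <- function(codon) GENETIC_CODE_STD[codon] == "*"

# Split a nucleotide string into codons; error if not in frame.
split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3L != 0L)
    stop_bad("sequence length %d is not divisible by 3", nchar(seq))
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

# Single-nucleotide neighbours of a codon at one position.
codon_neighbours <- function(codon, pos) {
  base <- substr(codon, pos, pos)
  alts <- setdiff(BASES, base)
  vapply(alts, function(b) {
    out <- codon
    substr(out, pos, pos) <- b
    out
  }, character(1), USE.NAMES = FALSE)
}

# Synonymous site count of one codon under NG86: at each position the
# fraction of the possible single-nucleotide changes (changes creating a
# stop codon are excluded from consideration) that preserve the amino acid.
# The nonsynonymous count is the complement, so S + N = 3 per codon.
codon_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    nb <- codon_neighbours(codon, pos)
    nb <- nb[!is_stop(nb)]
    if (length(nb) > 0)
      s <- s + sum(translate_codon(nb) == aa) / length(nb)
  }
  s
}

# Cache S per codon for the 61 sense codons.
.syn_site_table <- local({
  sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  vapply(sense, codon_syn_sites, numeric(1))
})

# Observed synonymous/nonsynonymous differences between two codons,
# averaged over all minimal substitution pathways.  Pathways passing
# through a stop codon are excluded; if every pathway is blocked the full
# set is used (never happens for sense codons differing at <= 2 sites in
# the standard code, but keeps 3-site corner cases defined).
codon_differences <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- if (k == 1L) list(diff_pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
      out
    }
    perms(diff_pos)
  }
  score_path <- function(ord) {
    cur <- c1
    sd <- 0; nd <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (is_stop(nxt)) return(NULL)
      if (translate_codon(nxt) == translate_codon(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  scored <- Filter(Negate(is.null), lapply(orders, score_path))
  if (length(scored) == 0L) {
    scored <- lapply(orders, function(ord) {
      cur <- c1; sd <- 0; nd <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        same <- !is_stop(nxt) && !is_stop(cur) &&
          translate_codon(nxt) == translate_codon(cur)
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, scored))
}

#' Nei-Gojobori (1986) Ka/Ks from an in-frame codon alignment
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon from the
#' standard genetic code (averaged over both sequences), partitions observed
#' differences by averaging over all minimal substitution pathways for
#' multi-difference codons, and applies the Jukes-Cantor correction
#' \eqn{K = -\frac{3}{4}\ln(1 - \frac{4}{3}p)} to the proportions
#' \eqn{p_S = S_d/S} and \eqn{p_N = N_d/N}.
#'
#' Codons containing gaps (`-`) or ambiguous bases are skipped in both
#' sequences. Internal stop codons are an error.
#'
#' @param seq_a,seq_b equal-length in-frame coding sequences (character
#'   strings, or character vectors of codons).
#' @return an object of class `ks_estimate`: list with elements `ka`, `ks`,
#'   `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `n_codons` (ungapped codons used) and
#'   `saturated` (`TRUE` when the log correction is undefined, i.e.
#'   \eqn{p \ge 3/4}; the corresponding `ka`/`ks` is then `NA`).
#' @examples
#' pair <- simulate_codon_pair(30, n_syn_changes = 3, n_nonsyn_changes = 1,
#'                             seed = 1)
#' ng86_ks(pair$seq_a, pair$seq_b)
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
ng86_ks <- function(seq_a, seq_b) {
  ca <- if (length(seq_a) > 1L) toupper(seq_a) else split_codons(seq_a)
  cb <- if (length(seq_b) > 1L) toupper(seq_b) else split_codons(seq_b)
  if (length(ca) != length(cb))
    stop_bad("sequences differ in codon count (%d vs %d)", length(ca), length(cb))
  ok <- grepl("^[TCAG]{3}$", ca) & grepl("^[TCAG]{3}$", cb)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) stop_bad("no ungapped codons in alignment")
  if (any(is_stop(ca)) || any(is_stop(cb)))
    stop_bad("internal stop codon in alignment")

  S <- (sum(.syn_site_table[ca]) + sum(.syn_site_table[cb])) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) codon_differences(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  out <- list(ka = jc(pN), ks = jc(pS), S = S, N = N, Sd = Sd, Nd = Nd,
              pS = pS, pN = pN, n_codons = length(ca),
              saturated = (pS >= 0.75) || (pN >= 0.75))
  class(out) <- "ks_estimate"
  out
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("NG86 estimate: Ka = %s, Ks = %s  (S = %.2f, N = %.2f, %d codons)%s\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              x$S, x$N, x$n_codons,
              if (x$saturated) "  [saturated]" else ""))
  invisible(x)
}
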