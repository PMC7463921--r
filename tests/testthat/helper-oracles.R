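# Brute-force grid-search oracle for the two-point F2 recombination
# fraction. The class probabilities are rebuilt from first principles by
# enumerating the four gamete haplotypes explicitly, independent of the
# package's collapsed-table implementation.

oracle_class_probs <- function(r, score_a, score_b) {
  # gamete haplotypes (allele at locus a, allele at locus b), 1 = parent-1
  gam <- rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 1))
  gp <- c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  obs_class <- function(g, score) {
    switch(score,
           co = g,
           dom1 = if (g <= 1) 0L else 2L,
           dom2 = if (g >= 1) 2L else 0L)
  }
  probs <- list()
  for (g1 in 1:4) for (g2 in 1:4) {
    ga <- (gam[g1, 1] - 1) + (gam[g2, 1] - 1)   # copies of parent-2 allele
    gb <- (gam[g1, 2] - 1) + (gam[g2, 2] - 1)
    key <- paste(obs_class(ga, score_a), obs_class(gb, score_b))
    probs[[key]] <- (probs[[key]] %||% 0) + gp[g1] * gp[g2]
  }
  probs
}

oracle_rf_grid <- function(calls_a, calls_b, score_a, score_b,
                           grid = seq(1e-4, 0.4999, by = 1e-4)) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  a <- calls_a[ok]; b <- calls_b[ok]
  key <- paste(a, b)
  counts <- table(key)
  ll <- vapply(grid, function(r) {
    p <- oracle_class_probs(r, score_a, score_b)
    sum(vapply(names(counts), function(k)
      counts[[k]] * log(p[[k]]), numeric(1)))
  }, numeric(1))
  grid[which.max(ll)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random simulated marker pair of given score types at true rf r
sim_marker_pair <- function(n, r, score_a, score_b, seed) {
  set.seed(seed)
  g1 <- sample(1:4, n, replace = TRUE, prob = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
  g2 <- sample(1:4, n, replace = TRUE, prob = c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2))
  hap <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  ga <- hap[g1, 1] + hap[g2, 1]
  gb <- hap[g1, 2] + hap[g2, 2]
  collapse <- function(g, score) {
    if (score == "co") return(as.integer(g))
    if (score == "dom1") return(ifelse(g <= 1, 0L, 2L))
    ifelse(g >= 1, 2L, 0L)
  }
  list(a = collapse(ga, score_a), b = collapse(gb, score_b))
}

spearman_abs <- function(x, y)
  abs(stats::cor(x, y, method = "spearman"))
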