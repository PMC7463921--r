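# Two-point recombination-fraction estimation for an F2 population.
#
# Gametes from the F1 carry parental haplotypes with probability (1-r)/2
# each and recombinant haplotypes with probability r/2 each; an F2 genotype
# is the sum of two independent gametes. Dominant (PAV) classes collapse the
# appropriate codominant cells: a marker scored "dom1" shows presence for
# genotype classes {0,1}, "dom2" for {1,2} (codes = copies of the parent-2
# allele).

# Joint F2 genotype probabilities at two phased loci.
f2_joint_probs <- function(r) {
  c_ <- 1 - r
  matrix(c(c_^2 / 4,        c_ * r / 2, r^2 / 4,
           c_ * r / 2, (c_^2 + r^2) / 2, c_ * r / 2,
           r^2 / 4,         c_ * r / 2, c_^2 / 4),
         3, 3, byrow = TRUE)
}

# Observable classes of a score type: list(codes, membership rows of the
# underlying genotype classes 0/1/2).
score_classes <- function(score) {
  switch(score,
    co   = list(codes = c(0L, 1L, 2L), member = list(1L, 2L, 3L)),
    dom1 = list(codes = c(0L, 2L),     member = list(c(1L, 2L), 3L)),
    dom2 = list(codes = c(0L, 2L),     member = list(1L, c(2L, 3L))),
    stop_bad("unknown score type '%s'", score))
}

# Class-pair probability table for two score types at recombination r.
cell_probs <- function(r, score_a, score_b) {
  J <- f2_joint_probs(r)
  ca <- score_classes(score_a); cb <- score_classes(score_b)
  out <- matrix(0, length(ca$codes), length(cb$codes),
                dimnames = list(ca$codes, cb$codes))
  for (u in seq_along(ca$codes))
    for (v in seq_along(cb$codes))
      out[u, v] <- sum(J[ca$member[[u]], cb$member[[v]]])
  out
}

#' Two-point ML recombination fraction between two phased F2 markers
#'
#' Maximises the F2 two-point likelihood over \eqn{r \in [0, 0.5]} for any
#' combination of codominant and dominant score types, with dominant classes
#' formed by collapsing the corresponding codominant cells. The LOD is the
#' log10 likelihood ratio against \eqn{r = 0.5}.
#'
#' @param calls_a,calls_b integer phased class codes (see
#'   [phase_genotypes()]); `NA` = missing.
#' @param score_a,score_b score types (`"co"`, `"dom1"`, `"dom2"`).
#' @param min_informative minimum number of individuals scored at both
#'   markers (default 10).
#' @return list (class `rf_estimate`) with `rf`, `lod`, `n_informative`.
#' @examples
#' sim <- simulate_f2_population(sim_map_config(n_linkage_groups = 1,
#'   lengths_cM = 20, n_markers_per_group = 2, frac_pav = 0,
#'   missing_rate = 0, error_rate = 0, n_individuals = 200))
#' ph <- phase_genotypes(sim$genotypes)
#' estimate_rf(ph$geno[, 1], ph$geno[, 2], "co", "co")
#' @export
estimate_rf <- function(calls_a, calls_b, score_a = "co", score_b = "co",
                        min_informative = 10L) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (sum(ok) == 0L) stop_bad("no informative individuals")
  if (sum(ok) < min_informative)
    stop_bad("only %d individuals scored at both markers (need >= %d)",
             sum(ok), min_informative)
  a <- calls_a[ok]; b <- calls_b[ok]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop_bad("monomorphic marker: recombination fraction undefined")
  ca <- score_classes(score_a); cb <- score_classes(score_b)
  counts <- matrix(0, length(ca$codes), length(cb$codes))
  for (u in seq_along(ca$codes))
    for (v in seq_along(cb$codes))
      counts[u, v] <- sum(a == ca$codes[u] & b == cb$codes[v])
  ll <- function(r) sum(counts * log(cell_probs(r, score_a, score_b)))
  opt <- stats::optimize(ll, c(1e-9, 0.5), maximum = TRUE, tol = 1e-8)
  # the optimum may sit on a boundary
  cand_r <- c(opt$maximum, 0, 0.5)
  cand_ll <- c(opt$objective, ll(0), ll(0.5))
  cand_ll[!is.finite(cand_ll)] <- -Inf
  best <- which.max(cand_ll)
  rf <- cand_r[best]
  lod <- max(0, (cand_ll[best] - ll(0.5)) / log(10))
  structure(list(rf = rf, lod = lod, n_informative = sum(ok)),
            class = "rf_estimate")
}

#' @export
print.rf_estimate <- function(x, ...) {
  cat(sprintf("rf = %.4f (LOD %.2f, n = %d)\n", x$rf, x$lod, x$n_informative))
  invisible(x)
}

#' Pairwise recombination fractions for a phased marker set
#'
#' Vectorised grid-search ML over all marker pairs: class-combination counts
#' are accumulated by indicator cross-products, then the two-point
#' log-likelihood is scanned over a grid of r values, so the whole matrix
#' costs a handful of BLAS calls per grid point. Precision is the grid step
#' (default 0.0025), ample for linkage grouping and ordering; use
#' [estimate_rf()] where continuous-ML precision matters.
#'
#' In addition to the ML estimate, the matrix `rf_up` holds the upper end
#' of the per-pair likelihood interval (largest r whose log-likelihood is
#' within `drop_ll` of the maximum). Poorly informative pairs — notably
#' dominant markers in repulsion — have wide intervals, and ordering on
#' `rf_up` rather than the raw estimate keeps their noisy point estimates
#' from being mistaken for tight linkage.
#'
#' @param geno integer matrix of phased codes (individuals x markers).
#' @param scores score type per marker.
#' @param grid r values scanned.
#' @param drop_ll log-likelihood drop defining the interval (default 1.92,
#'   the 95% chi-square cutoff).
#' @return list with matrices `rf`, `rf_up`, `lod` and `n` (individuals
#'   informative for each pair).
#' @export
rf_matrix <- function(geno, scores,
                      grid = c(1e-4, seq(0.0025, 0.4975, by = 0.0025)),
                      drop_ll = 1.92) {
  m <- ncol(geno)
  stopifnot(length(scores) == m)
  rf <- matrix(NA_real_, m, m, dimnames = list(colnames(geno), colnames(geno)))
  lod <- rf
  rf_up <- rf
  nmat <- matrix(0, m, m, dimnames = dimnames(rf))
  types <- unique(scores)
  ind <- lapply(types, function(tp) {
    cls <- score_classes(tp)
    cols <- which(scores == tp)
    mats <- lapply(cls$codes, function(cd) {
      M <- (geno[, cols, drop = FALSE] == cd)
      M[is.na(M)] <- FALSE
      storage.mode(M) <- "double"
      M
    })
    list(cols = cols, codes = cls$codes, mats = mats)
  })
  names(ind) <- types
  for (ta in types) for (tb in types) {
    A <- ind[[ta]]; B <- ind[[tb]]
    Ka <- length(A$codes); Kb <- length(B$codes)
    counts <- vector("list", Ka * Kb)
    for (u in seq_len(Ka)) for (v in seq_len(Kb))
      counts[[(u - 1) * Kb + v]] <- crossprod(A$mats[[u]], B$mats[[v]])
    ntot <- Reduce(`+`, counts)
    best_ll <- matrix(-Inf, length(A$cols), length(B$cols))
    best_r <- best_ll
    for (r in c(grid, 0.5)) {
      P <- cell_probs(r, ta, tb)
      llr <- 0
      for (u in seq_len(Ka)) for (v in seq_len(Kb))
        llr <- llr + counts[[(u - 1) * Kb + v]] * log(P[u, v])
      if (r == 0.5) {
        lod[A$cols, B$cols] <- pmax(0, (best_ll - llr) / log(10))
      } else {
        upd <- llr > best_ll
        best_ll[upd] <- llr[upd]
        best_r[upd] <- r
      }
    }
    rf[A$cols, B$cols] <- best_r
    nmat[A$cols, B$cols] <- ntot
    # second sweep: largest r still within drop_ll of the maximum
    up <- matrix(grid[1], length(A$cols), length(B$cols))
    for (r in grid) {
      P <- cell_probs(r, ta, tb)
      llr <- 0
      for (u in seq_len(Ka)) for (v in seq_len(Kb))
        llr <- llr + counts[[(u - 1) * Kb + v]] * log(P[u, v])
      ok <- llr >= best_ll - drop_ll
      up[ok] <- r
    }
    rf_up[A$cols, B$cols] <- up
  }
  diag(rf) <- 0
  diag(lod) <- 0
  diag(rf_up) <- 0
  list(rf = rf, rf_up = rf_up, lod = lod, n = nmat)
}

#' Kosambi mapping function
#'
#' Converts a recombination fraction to map distance,
#' \eqn{d = 25\,\ln\frac{1+2r}{1-2r}} centiMorgans, and back
#' (\eqn{r = \frac{1}{2}\tanh(d/50)}).
#'
#' @param rf recombination fraction in `[0, 0.5)`.
#' @return distance in cM.
#' @examples
#' kosambi(0.25)                    # 25 * log(3)
#' kosambi_inverse(kosambi(0.3))    # 0.3
#' @export
kosambi <- function(rf) {
  if (any(!is.finite(rf)) || any(rf < 0) || any(rf >= 0.5))
    stop_bad("rf must lie in [0, 0.5): distance is infinite at rf = 0.5")
  25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' @rdname kosambi
#' @param distance_cM map distance in centiMorgans.
#' @export
kosambi_inverse <- function(distance_cM) {
  if (any(!is.finite(distance_cM)) || any(distance_cM < 0))
    stop_bad("distance must be finite and >= 0")
  0.5 * tanh(distance_cM / 50)
}
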