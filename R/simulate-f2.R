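#' Configuration for the F2 population simulator
#'
#' Defaults emulate the study design behind the tedera map: ten linkage
#' groups with the published group lengths and marker totals (2042 markers,
#' ~41% dominant PAV), 185 F2 individuals plus two homozygous parents,
#' a 0.5% genotyping-error rate and 3% missing calls.
#'
#' @param n_linkage_groups number of linkage groups.
#' @param lengths_cM map length of each group (recycled).
#' @param n_markers_per_group markers per group (recycled).
#' @param frac_pav fraction of markers simulated as dominant PAV.
#' @param missing_rate per-call probability of a missing score.
#' @param error_rate per-call probability of a genotyping error.
#' @param n_individuals number of F2 individuals (>= 2).
#' @param seed integer seed.
#' @return a `sim_map_config` list.
#' @export
sim_map_config <- function(n_linkage_groups = 10,
                           lengths_cM = c(113.7, 109.3, 102.1, 95.3, 88.2,
                                          88.2, 85.9, 81.7, 80.0, 66.9),
                           n_markers_per_group = c(152, 264, 144, 298, 208,
                                                   209, 208, 225, 127, 207),
                           frac_pav = 0.41,
                           missing_rate = 0.03,
                           error_rate = 0.005,
                           n_individuals = 185,
                           seed = 1L) {
  cfg <- list(n_linkage_groups = n_linkage_groups,
              lengths_cM = rep_len(lengths_cM, n_linkage_groups),
              n_markers_per_group = rep_len(n_markers_per_group, n_linkage_groups),
              frac_pav = frac_pav, missing_rate = missing_rate,
              error_rate = error_rate, n_individuals = n_individuals,
              seed = seed)
  if (any(!is.finite(cfg$lengths_cM)) || any(cfg$lengths_cM < 0))
    stop_bad("lengths_cM must be finite and >= 0")
  probs <- c(frac_pav, missing_rate, error_rate)
  if (any(probs < 0 | probs > 1)) stop_bad("probabilities must lie in [0,1]")
  if (n_individuals < 2) stop_bad("n_individuals must be >= 2")
  class(cfg) <- "sim_map_config"
  cfg
}

# One gamete across a linkage group: crossovers as a Poisson process on the
# cM length (Haldane model, no interference).  Returns 1 (parent-1 allele)
# or 2 per marker position.
sim_gamete <- function(positions, length_cM) {
  n_co <- stats::rpois(1, length_cM / 100)
  start <- sample(1:2, 1)
  if (n_co == 0L) return(rep(start, length(positions)))
  xo <- sort(stats::runif(n_co, 0, length_cM))
  flips <- vapply(positions, function(p) sum(xo <= p), integer(1))
  1 + (start - 1 + flips) %% 2
}

#' Simulate an F2 mapping population with known map
#'
#' Generates an F2 population from a selfed F1 by dropping crossovers as a
#' Poisson process on each group's map length (no interference), then scores
#' each marker either codominantly (SNP: `AA`/`AB`/`BB`) or dominantly
#' (PAV: heterozygotes report `P`, matching dominance masking of the same
#' underlying genotypes). Genotyping errors flip calls to a random other
#' legal code at `error_rate`; calls go missing at `missing_rate`. Parents
#' are homozygous throughout (parent 1 carries the `A`/reference allele) and
#' are subject to the same error and missingness processes.
#'
#' @param cfg a [sim_map_config()].
#' @return list with
#'   `genotypes` (a [genotype_matrix()]),
#'   `true_map` (data frame: `marker`, `group`, `position_cM`, `type`,
#'   `presence_parent` — which parent carries the presence allele of a PAV),
#'   and `true_geno` (error-free integer genotypes of the F2 individuals,
#'   coded 0/1/2 = copies of the parent-2 allele).
#' @examples
#' sim <- simulate_f2_population(sim_map_config(n_linkage_groups = 2,
#'   lengths_cM = 50, n_markers_per_group = 20, n_individuals = 50))
#' sim$genotypes
#' @export
simulate_f2_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_map_config"))
  with_seed(derive_seed(cfg$seed, "f2"), {
    n <- cfg$n_individuals
    true_map <- do.call(rbind, lapply(seq_len(cfg$n_linkage_groups), function(g) {
      m <- cfg$n_markers_per_group[g]
      pos <- if (m == 1L) 0 else seq(0, cfg$lengths_cM[g], length.out = m)
      data.frame(marker = sprintf("G%02d_M%04d", g, seq_len(m)),
                 group = g, position_cM = pos, stringsAsFactors = FALSE)
    }))
    n_mark <- nrow(true_map)
    true_map$type <- ifelse(stats::runif(n_mark) < cfg$frac_pav, "PAV", "SNP")
    true_map$presence_parent <- ifelse(true_map$type == "PAV",
                                       sample(1:2, n_mark, replace = TRUE), NA)

    geno <- matrix(0L, n, n_mark)
    for (g in seq_len(cfg$n_linkage_groups)) {
      idx <- which(true_map$group == g)
      pos <- true_map$position_cM[idx]
      L <- cfg$lengths_cM[g]
      for (i in seq_len(n)) {
        gam <- sim_gamete(pos, L) + sim_gamete(pos, L)
        geno[i, idx] <- gam - 2L   # 0/1/2 copies of the parent-2 allele
      }
    }

    ind <- data.frame(
      id = c("P1", "P2", sprintf("F2_%03d", seq_len(n))),
      role = c("parent1", "parent2", rep("F2", n)),
      batch = c(NA, NA, paste0("Pool", 1 + (seq_len(n) - 1) %% 4)),
      stringsAsFactors = FALSE)
    full <- rbind(0L, 2L, geno)  # parent rows on top

    calls <- matrix("", nrow(full), n_mark)
    for (j in seq_len(n_mark)) {
      if (true_map$type[j] == "SNP") {
        calls[, j] <- c("AA", "AB", "BB")[full[, j] + 1L]
      } else if (true_map$presence_parent[j] == 1) {
        calls[, j] <- ifelse(full[, j] <= 1L, "P", "A")
      } else {
        calls[, j] <- ifelse(full[, j] >= 1L, "P", "A")
      }
    }

    if (cfg$error_rate > 0) {
      for (j in seq_len(n_mark)) {
        codes <- if (true_map$type[j] == "SNP") c("AA", "AB", "BB") else c("P", "A")
        hit <- which(stats::runif(nrow(calls)) < cfg$error_rate)
        for (i in hit)
          calls[i, j] <- sample(setdiff(codes, calls[i, j]), 1)
      }
    }
    if (cfg$missing_rate > 0)
      calls[stats::runif(length(calls)) < cfg$missing_rate] <- "NN"

    gm <- genotype_matrix(calls, ind,
                          data.frame(id = true_map$marker, type = true_map$type,
                                     stringsAsFactors = FALSE))
    rownames(geno) <- ind$id[ind$role == "F2"]
    colnames(geno) <- true_map$marker
    list(genotypes = gm, true_map = true_map, true_geno = geno)
  })
}
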