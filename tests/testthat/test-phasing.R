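test_that("fully informative parents phase a SNP directly", {
  r <- phase_snp(c("AA", "BB"), c("AA", "AB", "BB", "NN"))
  expect_equal(r$status, "resolved")
  expect_equal(r$phased, c(0L, 1L, 2L, NA))
})

test_that("a heterozygous parent is phased via the homozygous one", {
  # parent 2 is AA, so BB must be the parent-1 homozygote class
  r <- phase_snp(c("AB", "AA"), c("BB", "AA", "AB"))
  expect_equal(r$status, "resolved")
  expect_equal(r$phased, c(0L, 2L, 1L))
})

test_that("both-heterozygous parents leave dual-retained allele swaps", {
  r <- phase_snp(c("AB", "AB"), c("AA", "BB", "AB"))
  expect_equal(r$status, "dual")
  # candidate 2 is the exact allele swap of candidate 1
  expect_equal(2L - r$phased, c(2L, 0L, 1L))
})

test_that("inconsistent and monomorphic SNPs are excluded", {
  expect_equal(phase_snp(c("AA", "AA"), c("AA", "BB", "AB"))$reason,
               "inconsistent_parents")
  expect_equal(phase_snp(c("AA", "BB"), c("AA", "AA", "NN"))$reason,
               "monomorphic")
})

test_that("PAV phasing follows the presence-carrying parent", {
  r <- phase_pav(c("P", "A"), c("P", "A", "NN", "P"))
  expect_equal(r$status, "resolved")
  expect_equal(r$score, "dom1")
  expect_equal(r$phased, c(0L, 2L, NA, 0L))
  # absent parent 1 pins presence on parent 2 even if parent 2 is missing
  r2 <- phase_pav(c("A", "NN"), c("P", "A"))
  expect_equal(r2$score, "dom2")
})

test_that("both-present parents give dual-retained PAVs; both-absent exclude", {
  expect_equal(phase_pav(c("P", "P"), c("P", "A"))$status, "dual")
  expect_equal(phase_pav(c("A", "A"), c("P", "A"))$reason,
               "inconsistent_parents")
  expect_equal(phase_pav(c("P", "A"), c("P", "P", "P"))$reason, "monomorphic")
})

test_that("phasing never alters missingness", {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = 1, lengths_cM = 30, n_markers_per_group = 20,
    missing_rate = 0.2, error_rate = 0, n_individuals = 40, seed = 6))
  ph <- phase_genotypes(sim$genotypes)
  f2_calls <- sim$genotypes$calls[sim$genotypes$individuals$role == "F2",
                                  ph$markers$id, drop = FALSE]
  expect_identical(unname(is.na(ph$geno)), unname(f2_calls == "NN"))
})

test_that("resolve_dual_phase picks the low-rf candidate", {
  sim <- sim_marker_pair(200, 0.05, "co", "co", seed = 21)
  res <- resolve_dual_phase(sim$a, "co",
                            matrix(sim$b, ncol = 1), "co")
  expect_equal(res$choice, 1L)
  # handing in the swapped candidate must flip the choice
  res2 <- resolve_dual_phase(2L - sim$a, "co", matrix(sim$b, ncol = 1), "co")
  expect_equal(res2$choice, 2L)
  expect_equal(res2$phased, sim$a)
})

test_that("dual-phase resolution recovers the true phase at 5 cM spacing", {
  # scaled-down Monte-Carlo: 100 dual markers against one phased neighbour
  n_ok <- 0
  for (k in 1:100) {
    r <- kosambi_inverse(5)
    pair <- sim_marker_pair(178, r, "co", "co", seed = 1000 + k)
    flip <- k %% 2 == 0
    cand <- if (flip) 2L - pair$a else pair$a
    res <- resolve_dual_phase(cand, "co", matrix(pair$b, ncol = 1), "co")
    recovered <- identical(res$phased, pair$a)
    n_ok <- n_ok + recovered
  }
  expect_gte(n_ok, 97)
})

test_that("resolution without neighbours fails loudly", {
  expect_error(resolve_dual_phase(c(0L, 1L), "co",
                                  matrix(integer(0), nrow = 2), character(0)),
               "no phased neighbours")
})

test_that("double-crossover outliers are flagged and clean data is not", {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = 1, lengths_cM = 60, n_markers_per_group = 40,
    frac_pav = 0, missing_rate = 0, error_rate = 0, n_individuals = 60,
    seed = 14))
  ph <- phase_genotypes(sim$genotypes)
  ord <- list(sim$true_map$marker)
  clean <- flag_problem_individuals(ph, ord)
  expect_false(any(clean$flagged))
  # inject 10% call errors into one individual
  bad <- ph
  set.seed(1)
  hit <- sample(ncol(bad$geno), round(0.1 * ncol(bad$geno)))
  bad$geno[5, hit] <- (bad$geno[5, hit] + 1L) %% 3L
  flagged <- flag_problem_individuals(bad, ord)
  expect_true(flagged$flagged[5])
  expect_lte(sum(flagged$flagged), 2)
})

test_that("flagging is invariant to order reversal and needs a baseline", {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = 1, lengths_cM = 40, n_markers_per_group = 25,
    frac_pav = 0, n_individuals = 30, seed = 2))
  ph <- phase_genotypes(sim$genotypes)
  ord <- intersect(sim$true_map$marker, colnames(ph$geno))
  a <- flag_problem_individuals(ph, list(ord))
  b <- flag_problem_individuals(ph, list(rev(ord)))
  expect_identical(a, b)
  tiny <- ph; tiny$geno <- tiny$geno[1:4, , drop = FALSE]
  expect_error(flag_problem_individuals(tiny, list(ord)), "fewer than 5")
})

test_that("PAV batch dropping and missingness filtering work", {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = 1, lengths_cM = 30, n_markers_per_group = 20,
    frac_pav = 0.5, missing_rate = 0.1, n_individuals = 40, seed = 4))
  gm <- sim$genotypes
  out <- filter_pav_by_missingness(gm, max_missing = 1, drop_batches = "Pool1")
  pool1 <- !is.na(out$individuals$batch) & out$individuals$batch == "Pool1"
  pav <- out$markers$type == "PAV"
  expect_true(all(out$calls[pool1, pav] == "NN"))
  snp <- out$markers$type == "SNP"
  expect_identical(out$calls[, out$markers$id[snp]],
                   gm$calls[, gm$markers$id[snp]])
  # max_missing = 0 removes every PAV with any missing call
  strict <- filter_pav_by_missingness(gm, max_missing = 0)
  f2 <- strict$individuals$role == "F2"
  kept_pav <- strict$markers$type == "PAV"
  expect_true(all(colSums(strict$calls[f2, kept_pav, drop = FALSE] == "NN") == 0))
  # max_missing = 1 removes none
  lax <- filter_pav_by_missingness(gm, max_missing = 1)
  expect_equal(nrow(lax$markers), nrow(gm$markers))
  expect_error(filter_pav_by_missingness(gm, drop_batches = "PoolX"),
               "unknown batch")
})
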