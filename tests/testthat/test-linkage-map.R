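make_phased <- function(n_groups = 3, lengths = 50, m = 20, n = 150, seed = 5,
                        frac_pav = 0.4, error = 0.005) {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = n_groups, lengths_cM = lengths,
    n_markers_per_group = m, frac_pav = frac_pav, missing_rate = 0.03,
    error_rate = error, n_individuals = n, seed = seed))
  list(sim = sim, ph = phase_genotypes(sim$genotypes))
}

test_that("clustering recovers simulated groups pure and complete", {
  x <- make_phased(n_groups = 3, m = 15, seed = 31)
  sc <- stats::setNames(x$ph$markers$score, x$ph$markers$id)
  est <- rf_matrix(x$ph$geno, sc)
  cl <- cluster_markers(est$rf, est$lod)
  expect_equal(length(cl$groups), 3)
  for (g in cl$groups) {
    tg <- x$sim$true_map$group[match(g, x$sim$true_map$marker)]
    expect_equal(length(unique(tg)), 1)
  }
})

test_that("tightly linked pairs group together, unlinked markers stay out", {
  rf <- matrix(0.5, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  lod <- matrix(0, 6, 6, dimnames = dimnames(rf))
  link <- function(i, j, r) {
    rf[i, j] <<- rf[j, i] <<- r
    lod[i, j] <<- lod[j, i] <<- 10
  }
  link(1, 2, 0.05); link(2, 3, 0.08); link(3, 4, 0.18)
  link(5, 6, 0.05)
  diag(rf) <- 0
  cl <- cluster_markers(rf, lod, min_size = 2)
  grp_of <- function(m) which(vapply(cl$groups, function(g) m %in% g, logical(1)))
  expect_equal(grp_of("a"), grp_of("b"))
  expect_equal(grp_of("c"), grp_of("d"))   # joined at the 0.20 threshold
  expect_false(grp_of("a") == grp_of("e"))
  # a marker at rf >= 0.25 to everything is unplaced
  rf2 <- rbind(cbind(rf, g = 0.3), g = c(rep(0.3, 6), 0))
  colnames(rf2)[7] <- rownames(rf2)[7] <- "g"
  lod2 <- rbind(cbind(lod, g = 10), g = c(rep(10, 6), 0))
  colnames(lod2)[7] <- rownames(lod2)[7] <- "g"
  cl2 <- cluster_markers(rf2, lod2, min_size = 2)
  expect_true("g" %in% cl2$unplaced)
})

test_that("redundant binning pools identical patterns, missing is wildcard", {
  g <- cbind(a = c(0L, 1L, 2L, 1L, 0L),
             b = c(0L, 1L, 2L, 1L, 0L),        # duplicate of a
             c = c(0L, 1L, 2L, NA, 0L),        # compatible via missing
             d = c(0L, 1L, 2L, 1L, 2L))        # one conflicting call
  bn <- bin_redundant(g, rep("co", 4))
  expect_equal(sort(bn$bins[["a"]]), c("a", "b", "c"))
  expect_true("d" %in% bn$representatives)
  expect_equal(length(bn$representatives), 2)
})

test_that("three-marker ordering equals exhaustive enumeration", {
  D <- matrix(c(0, 5, 9,
                5, 0, 3,
                9, 3, 0), 3, 3)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3))
  costs <- vapply(perms, function(p) psoramap:::order_cost(D, p), numeric(1))
  best <- perms[[which.min(costs)]]
  got <- psoramap:::seriate_order(D, rep(TRUE, 3))
  same <- identical(got, best) || identical(rev(got), best)
  expect_true(same)
})

test_that("ordering recovers 20 evenly spaced markers up to reversal", {
  ok <- 0
  for (seed in 1:5) {
    sim <- simulate_f2_population(sim_map_config(
      n_linkage_groups = 1, lengths_cM = 38, n_markers_per_group = 20,
      frac_pav = 0, missing_rate = 0, error_rate = 0.005,
      n_individuals = 178, seed = 500 + seed))
    ph <- phase_genotypes(sim$genotypes)
    sc <- stats::setNames(ph$markers$score, ph$markers$id)
    est <- rf_matrix(ph$geno, sc)
    D <- kosambi(pmin(est$rf_up, 0.45))
    ord <- psoramap:::seriate_order(D, sc == "co")
    ids <- colnames(ph$geno)[ord]
    truth_rank <- match(ids, sim$true_map$marker)
    ok <- ok + (identical(truth_rank, seq_len(20L)) ||
                  identical(truth_rank, rev(seq_len(20L))))
  }
  expect_gte(ok, 4)   # >= 95% in the full-size study; 4/5 at this scale
})

test_that("a marker duplicating its neighbour has stability 1", {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = 1, lengths_cM = 40, n_markers_per_group = 6,
    frac_pav = 0, missing_rate = 0, error_rate = 0, n_individuals = 120,
    seed = 77))
  ph <- phase_genotypes(sim$genotypes)
  g <- cbind(ph$geno, dup = ph$geno[, 3])
  colnames(g)[7] <- "dup"
  sc <- rep("co", 7)
  osk <- order_skeleton(g, sc, n_jackknife = 10, seed = 2)
  expect_equal(unname(osk$stability[["dup"]]), 1)
})

test_that("attachment assigns the interval minimising summed rf", {
  skel <- c("s1", "s2", "s3")
  # marker simulated between s2 (2 cM away) and s3 (3 cM away)
  expect_equal(attach_interval(c(0.15, 0.02, 0.03), skel)[c("left", "right")],
               list(left = "s2", right = "s3"))
  # a copy of a skeleton marker attaches at zero distance to it
  iv <- attach_interval(c(0, 0.05, 0.2), skel)
  expect_true(iv$left == "s1" && iv$rf_sum <= 0.1)
  # unlinked marker is unplaced
  expect_null(attach_interval(c(0.4, 0.45, 0.5), skel))
})

test_that("map summary arithmetic and degenerate groups", {
  rows <- data.frame(group = "g1", skeleton = 2, redundant = 0, attached = 0,
                     length_cM = 5, max_interval_cM = 5)
  s <- map_summary_table(rows)
  expect_equal(s$mean_interval_cM[1], 5.00)
  expect_equal(s$max_interval_cM[1], 5)
  one <- map_summary_table(data.frame(group = "g1", skeleton = 1, redundant = 2,
                                      attached = 0, length_cM = 0))
  expect_true(is.na(one$mean_interval_cM[1]))
})

test_that("full map build conserves markers and places them correctly", {
  x <- make_phased(n_groups = 3, m = 25, n = 150, seed = 41)
  map <- build_linkage_map(x$ph, n_jackknife = 10, seed = 1)
  cls <- map$classes
  # conservation: every phased marker in exactly one class
  expect_equal(nrow(cls), ncol(x$ph$geno))
  expect_true(all(cls$class %in% c("skeleton", "redundant", "attached", "unplaced")))
  counts <- table(cls$class)
  expect_equal(sum(counts), ncol(x$ph$geno))
  # group purity of placed markers
  placed <- cls[cls$class != "unplaced", ]
  tg <- x$sim$true_map$group[match(placed$marker, x$sim$true_map$marker)]
  purity <- mean(vapply(split(tg, placed$group), function(v)
    max(table(v)) / length(v), numeric(1)))
  expect_gt(purity, 0.95)
  # skeleton order against truth
  for (g in map$groups) {
    tm <- x$sim$true_map[match(g$skeleton$marker, x$sim$true_map$marker), ]
    expect_gt(spearman_abs(tm$position_cM, g$skeleton$position_cM), 0.97)
  }
  # summary is invariant to reversing a group
  s1 <- summarize_map(map)
  rev_map <- map
  sk <- rev_map$groups[[1]]$skeleton
  rev_map$groups[[1]]$skeleton <- data.frame(
    marker = rev(sk$marker),
    position_cM = max(sk$position_cM) - rev(sk$position_cM))
  expect_equal(summarize_map(rev_map), s1)
})

test_that("map files are written and re-readable", {
  x <- make_phased(n_groups = 2, m = 12, n = 100, seed = 55)
  map <- build_linkage_map(x$ph, n_jackknife = 5, seed = 1)
  prefix <- withr::local_tempfile()
  files <- write_map(map, prefix)
  tab <- utils::read.delim(files[1])
  expect_setequal(unique(tab$class),
                  intersect(c("skeleton", "redundant", "attached"),
                            unique(map$classes$class)))
  expect_equal(sum(tab$class == "skeleton"),
               sum(vapply(map$groups, function(g) nrow(g$skeleton), integer(1))))
})
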