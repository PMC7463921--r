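blast_row <- function(q, s, evalue, bits = 60, pident = 90, sstart = 100,
                      send = 189) {
  sprintf("%s\t%s\t%.2f\t30\t3\t0\t1\t90\t%d\t%d\t%g\t%.1f",
          q, s, pident, sstart, send, evalue, bits)
}

chrlens <- data.frame(name = c("Pv01", "Pv02"), length_bp = c(5e6, 5e6))

test_that("tabular parsing applies the e-value cut and unanchored filter", {
  f <- withr::local_tempfile()
  writeLines(c(blast_row("m1", "Pv01", 1e-20),
               blast_row("m2", "scaffold_123", 1e-20),
               blast_row("m3", "Pv02", 9e-6),
               blast_row("m4", "Pv01", 2e-5)), f)
  m <- read_blast_tabular(f, chrlens)
  expect_setequal(m$qseqid, c("m1", "m3"))     # 9e-6 kept, 2e-5 and scaffold dropped
  d <- attr(m, "dropped")
  expect_equal(d$parsed, 4)
  expect_equal(d$evalue, 1)
  expect_equal(d$unanchored, 1)
})

test_that("malformed rows and reversed strands are handled", {
  f <- withr::local_tempfile()
  writeLines(c(blast_row("m1", "Pv01", 1e-10),
               "m2\tPv01\tonly\televen\tcolumns\t0\t1\t90\t5\t99\t1e-10"), f)
  expect_error(read_blast_tabular(f, chrlens), "line 2")
  f2 <- withr::local_tempfile()
  writeLines(blast_row("m1", "Pv01", 1e-10, sstart = 500, send = 411), f2)
  m <- read_blast_tabular(f2, chrlens)
  expect_equal(m$sstart, 411)
  expect_equal(m$send, 500)
  expect_equal(m$orientation, "-")
})

test_that("top-hit filtering follows the WGD two-stage rule", {
  mk <- function(q, s, e) data.frame(qseqid = q, sseqid = s, pident = 90,
                                     length = 30, mismatch = 0, gapopen = 0,
                                     qstart = 1, qend = 90, sstart = 1,
                                     send = 90, evalue = e, bitscore = 50)
  one <- mk("m1", "chrA", 1e-9)
  expect_equal(nrow(filter_top_hits(one, FALSE)), 1)
  expect_equal(nrow(filter_top_hits(one, TRUE)), 1)
  three <- rbind(mk("m1", "chrA", 1e-20), mk("m1", "chrB", 1e-15),
                 mk("m1", "chrC", 1e-8))
  non <- filter_top_hits(three, FALSE)
  expect_equal(non$sseqid, "chrA")
  wgd <- filter_top_hits(three, TRUE)
  expect_setequal(wgd$sseqid, c("chrA", "chrB"))
  # two hits on one chromosome collapse in stage 1
  dup <- rbind(mk("m1", "chrA", 1e-20), mk("m1", "chrA", 1e-10))
  expect_equal(nrow(filter_top_hits(dup, TRUE)), 1)
  expect_equal(filter_top_hits(dup, TRUE)$evalue, 1e-20)
})

test_that("the published five-pairing worked example removes only Bb04xPv02", {
  ex <- data.frame(qseqid = paste0("m", 1:5), sseqid = "Pv02",
                   sstart = (1:5) * 1000, send = (1:5) * 1000 + 89,
                   linkage_group = c("Bb07", "Bb07", "Bb04", "Bb07", "Bb07"))
  out <- remove_isolated(ex)
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "removed")$linkage_group, "Bb04")
  expect_false("Bb04" %in% out$linkage_group)
})

test_that("uniform and alternating pairings survive the isolated filter", {
  same <- data.frame(qseqid = paste0("m", 1:5), sseqid = "Pv02",
                     sstart = (1:5) * 1000, send = (1:5) * 1000 + 89,
                     linkage_group = "Bb07")
  expect_equal(nrow(remove_isolated(same)), 5)
  alt <- same
  alt$linkage_group <- c("A", "B", "A", "B", "A")
  expect_equal(nrow(remove_isolated(alt)), 5)
  expect_warning(remove_isolated(same[1:3, ]), "fewer than 5")
})

test_that("isolated flags match a brute-force window oracle", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    m <- data.frame(qseqid = sprintf("m%02d", 1:n),
                    sseqid = sample(c("c1", "c2"), n, TRUE),
                    sstart = sample(1e6, n), linkage_group = sample(c("L1", "L2", "L3"), n, TRUE))
    m$send <- m$sstart + 89
    out <- remove_isolated(m)
    # oracle: same rule, written longhand over the sorted list
    ord <- order(match(m$sseqid, sort(unique(m$sseqid))),
                 (m$sstart + m$send) / 2, m$qseqid)
    sorted <- m[ord, ]
    pair <- paste(sorted$linkage_group, sorted$sseqid)
    drop <- logical(n)
    for (i in seq_len(n)) {
      win <- setdiff(max(1, i - 2):min(n, i + 2), i)
      drop[i] <- all(pair[win] != pair[i])
    }
    expect_equal(nrow(out), n - sum(drop))
    expect_setequal(attr(out, "removed")$qseqid, sorted$qseqid[drop])
  }
})

test_that("coordinate concatenation offsets chromosomes and groups", {
  m <- data.frame(qseqid = c("m1", "m2"), sseqid = c("Pv1", "Pv2"),
                  sstart = c(10, 1), send = c(10, 1),
                  linkage_group = c("L1", "L2"), position_cM = c(0.5, 2))
  cl <- data.frame(name = c("Pv1", "Pv2"), length_bp = c(100, 50))
  gl <- data.frame(group = c("L1", "L2"), length_cM = c(10, 20))
  al <- concatenate_coordinates(m, cl, gl)
  expect_equal(al$matches$x, c(10, 101))
  expect_equal(al$matches$y, c(0.5, 12))
  bad <- m; bad$sseqid[1] <- "PvX"
  expect_error(concatenate_coordinates(bad, cl, gl), "unknown chromosome")
})

test_that("dotplot data file conserves the retained match count", {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = 2, lengths_cM = 60, n_markers_per_group = 40,
    n_individuals = 30, seed = 3))
  mm <- simulate_marker_matches(sim$true_map,
                                sim_genome_config(n_chromosomes = 2, seed = 5))
  m <- join_map_positions(mm$matches,
                          data.frame(marker = sim$true_map$marker,
                                     group = sim$true_map$group,
                                     position_cM = sim$true_map$position_cM))
  al <- concatenate_coordinates(m, mm$chromosome_lengths,
                                data.frame(group = 1:2, length_cM = c(60, 60)))
  prefix <- withr::local_tempfile()
  files <- write_dotplot(al, prefix)
  lines <- readLines(files[1])
  pts <- grepl("^[0-9]", lines)
  expect_equal(sum(pts), nrow(al$matches))
  expect_error(write_dotplot(
    structure(list(matches = al$matches[0, ], chrom_offsets = al$chrom_offsets,
                   group_offsets = al$group_offsets),
              class = "synteny_alignment"), withr::local_tempfile()), "empty")
})

test_that("simulated matches are collinear, invertible and WGD-duplicated", {
  sim <- simulate_f2_population(sim_map_config(
    n_linkage_groups = 2, lengths_cM = 50, n_markers_per_group = 30,
    n_individuals = 20, seed = 9))
  base <- simulate_marker_matches(sim$true_map,
                                  sim_genome_config(n_chromosomes = 2, seed = 1))
  # identity layout: per-chromosome positions monotone in cM
  tr <- base$truth
  for (ch in unique(tr$chr)) {
    sub <- tr[tr$chr == ch & !tr$is_noise, ]
    cm <- sim$true_map$position_cM[match(sub$qseqid, sim$true_map$marker)]
    expect_true(all(diff(sub$position[order(cm)]) > 0))
  }
  # inversion flips exactly the covered markers
  inv_cfg <- sim_genome_config(n_chromosomes = 2,
    rearrangement_ops = list(list(type = "inversion", chr = "chr01",
                                  start = 1e7, end = 3e7)), seed = 1)
  inv <- simulate_marker_matches(sim$true_map, inv_cfg)
  flipped <- grepl(":inv", inv$truth$block)
  expect_true(any(flipped))
  expect_equal(inv$truth$position[flipped],
               1e7 + 3e7 - base$truth$position[flipped])
  expect_equal(inv$truth$position[!flipped], base$truth$position[!flipped])
  # WGD doubles every non-noise marker
  wgd <- simulate_marker_matches(sim$true_map,
                                 sim_genome_config(n_chromosomes = 2, wgd = TRUE,
                                                   seed = 1))
  nn <- wgd$truth[!wgd$truth$is_noise, ]
  expect_equal(nrow(nn), 2 * nrow(sim$true_map))
  expect_true(all(table(nn$qseqid) == 2))
  # invalid breakpoints rejected
  expect_error(simulate_marker_matches(sim$true_map,
    sim_genome_config(n_chromosomes = 2,
      rearrangement_ops = list(list(type = "inversion", chr = "chr01",
                                    start = 1, end = 9e9)))),
    "breakpoints outside")
})

test_that("per-stage drop counts sum to the parsed count (conservation audit)", {
  for (seed in c(2, 5, 8)) {
    sim <- simulate_f2_population(sim_map_config(
      n_linkage_groups = 3, lengths_cM = 60, n_markers_per_group = 40,
      n_individuals = 20, seed = seed))
    mm <- simulate_marker_matches(sim$true_map,
      sim_genome_config(n_chromosomes = 3, wgd = seed %% 2 == 0,
                        noise_match_rate = 0.1, seed = seed))
    f <- withr::local_tempfile()
    write_blast_tabular(mm$matches, f)
    parsed <- read_blast_tabular(f, mm$chromosome_lengths)
    d0 <- attr(parsed, "dropped")
    top <- filter_top_hits(parsed, wgd_mode = seed %% 2 == 0)
    joined <- join_map_positions(top, data.frame(
      marker = sim$true_map$marker, group = sim$true_map$group,
      position_cM = sim$true_map$position_cM))
    final <- remove_isolated(joined)
    expect_equal(d0$parsed,
                 nrow(final) + attr(final, "dropped") + attr(joined, "dropped") +
                   attr(top, "dropped") + d0$evalue + d0$unanchored)
  }
})
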