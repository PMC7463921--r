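#' Configuration for the marker-to-genome match simulator
#'
#' @param n_chromosomes number of target chromosomes.
#' @param chromosome_lengths_bp lengths in bp (recycled).
#' @param rearrangement_ops list of operations applied in order to the
#'   ancestral layout; each a list with `type` in
#'   `"inversion"` (`chr`, `start`, `end`),
#'   `"translocation"` (`chr`, `start`, `end`, `to_chr`, `to_pos`) or
#'   `"fission"` (`chr`, `breakpoint` — the distal segment moves to a new
#'   chromosome named `<chr>b`).
#' @param wgd if `TRUE` the whole chromosome set is duplicated (names with a
#'   `d` suffix) and every marker gains a second, independently perturbed
#'   hit.
#' @param noise_match_rate fraction of extra spurious hits emitted, relative
#'   to the number of true hits.
#' @param seed integer seed.
#' @return a `sim_genome_config` list.
#' @export
sim_genome_config <- function(n_chromosomes = 10,
                              chromosome_lengths_bp = 5e7,
                              rearrangement_ops = list(),
                              wgd = FALSE,
                              noise_match_rate = 0,
                              seed = 1L) {
  cfg <- list(n_chromosomes = n_chromosomes,
              chromosome_lengths_bp = rep_len(chromosome_lengths_bp, n_chromosomes),
              rearrangement_ops = rearrangement_ops,
              wgd = isTRUE(wgd), noise_match_rate = noise_match_rate,
              seed = seed)
  if (noise_match_rate < 0 || noise_match_rate > 1)
    stop_bad("noise_match_rate must lie in [0,1]")
  class(cfg) <- "sim_genome_config"
  cfg
}

#' Simulate translated-BLAST matches of map markers against a genome
#'
#' Lays the linkage groups collinearly onto the chromosomes (group g on
#' chromosome `1 + (g-1) %% n_chromosomes`, groups sharing a chromosome in
#' consecutive segments), applies the configured rearrangements, optionally
#' duplicates the genome (WGD), and emits 12-column BLAST-tabular rows.
#' True-hit e-values are drawn log-uniform over \[1e-9, 9e-6\] (matching the
#' empirical range of translated 90-bp tag hits); noise hits are extra rows
#' at uniform genomic positions with e-values log-uniform over
#' \[1e-6, 1e-5\], so they pass the significance cut and can beat a weak
#' true hit, leaving the isolated-match window filter as the remover.
#'
#' @param map data frame with `marker`, `group`, `position_cM` (e.g.
#'   `true_map` from [simulate_f2_population()]).
#' @param cfg a [sim_genome_config()].
#' @return list with `matches` (BLAST tabular data frame), `truth` (one row
#'   per emitted match: `qseqid`, `sseqid`, `position`, `is_noise`, `copy`,
#'   `block`), and `chromosome_lengths` (including chromosomes created by
#'   fission or WGD).
#' @export
simulate_marker_matches <- function(map, cfg) {
  stopifnot(inherits(cfg, "sim_genome_config"))
  if (nrow(map) == 0L) stop_bad("empty map")
  with_seed(derive_seed(cfg$seed, "genome"), {
    chroms <- data.frame(name = sprintf("chr%02d", seq_len(cfg$n_chromosomes)),
                         length_bp = cfg$chromosome_lengths_bp,
                         stringsAsFactors = FALSE)
    groups <- sort(unique(map$group))
    chr_of <- 1L + (seq_along(groups) - 1L) %% cfg$n_chromosomes
    per_chr <- table(chr_of)

    pos <- data.frame(qseqid = map$marker, chr = NA_character_,
                      bp = NA_real_, block = NA_character_,
                      stringsAsFactors = FALSE)
    for (k in seq_along(groups)) {
      idx <- which(map$group == groups[k])
      ci <- chr_of[k]
      slot <- sum(chr_of[seq_len(k)] == ci)          # which segment on ci
      seg_len <- chroms$length_bp[ci] / per_chr[[as.character(ci)]]
      seg_start <- (slot - 1) * seg_len
      span <- max(map$position_cM[idx], 1e-9)
      pos$chr[idx] <- chroms$name[ci]
      pos$bp[idx] <- seg_start + 1 +
        (map$position_cM[idx] / span) * (seg_len - 200)
      pos$block[idx] <- sprintf("%s>%s", groups[k], chroms$name[ci])
    }

    for (op in cfg$rearrangement_ops) {
      clen <- chroms$length_bp[match(op$chr, chroms$name)]
      if (is.na(clen)) stop_bad("rearrangement references unknown chromosome %s", op$chr)
      if (op$type == "inversion") {
        if (op$start < 1 || op$end > clen || op$start >= op$end)
          stop_bad("inversion breakpoints outside chromosome %s", op$chr)
        hit <- pos$chr == op$chr & pos$bp >= op$start & pos$bp <= op$end
        pos$bp[hit] <- op$start + op$end - pos$bp[hit]
        pos$block[hit] <- paste0(pos$block[hit], ":inv")
      } else if (op$type == "translocation") {
        if (op$start < 1 || op$end > clen || op$start >= op$end)
          stop_bad("translocation breakpoints outside chromosome %s", op$chr)
        tlen <- chroms$length_bp[match(op$to_chr, chroms$name)]
        if (is.na(tlen)) stop_bad("translocation target %s unknown", op$to_chr)
        if (op$to_pos < 1 || op$to_pos + (op$end - op$start) > tlen)
          stop_bad("translocation lands outside chromosome %s", op$to_chr)
        hit <- pos$chr == op$chr & pos$bp >= op$start & pos$bp <= op$end
        pos$bp[hit] <- op$to_pos + (pos$bp[hit] - op$start)
        pos$chr[hit] <- op$to_chr
        pos$block[hit] <- paste0(pos$block[hit], ">", op$to_chr)
      } else if (op$type == "fission") {
        if (op$breakpoint < 1 || op$breakpoint >= clen)
          stop_bad("fission breakpoint outside chromosome %s", op$chr)
        newname <- paste0(op$chr, "b")
        chroms <- rbind(chroms, data.frame(name = newname,
                                           length_bp = clen - op$breakpoint))
        hit <- pos$chr == op$chr & pos$bp > op$breakpoint
        pos$bp[hit] <- pos$bp[hit] - op$breakpoint
        pos$chr[hit] <- newname
        pos$block[hit] <- paste0(pos$block[hit], ">", newname)
        chroms$length_bp[chroms$name == op$chr] <- op$breakpoint
      } else stop_bad("unknown rearrangement type '%s'", op$type)
    }

    truth <- cbind(pos, is_noise = FALSE, copy = 1L)
    if (cfg$wgd) {
      dup <- chroms
      dup$name <- paste0(dup$name, "d")
      chroms <- rbind(chroms, dup)
      second <- pos
      second$chr <- paste0(second$chr, "d")
      jit <- stats::runif(nrow(second), -2e4, 2e4)
      lens <- chroms$length_bp[match(second$chr, chroms$name)]
      second$bp <- pmin(pmax(second$bp + jit, 1), lens - 100)
      second$block <- paste0(second$block, "(wgd)")
      truth <- rbind(truth, cbind(second, is_noise = FALSE, copy = 2L))
    }

    n_noise <- round(cfg$noise_match_rate * nrow(truth))
    if (n_noise > 0) {
      ni <- sample(nrow(map), n_noise, replace = TRUE)
      nc <- sample(nrow(chroms), n_noise, replace = TRUE)
      noise <- data.frame(qseqid = map$marker[ni],
                          chr = chroms$name[nc],
                          bp = stats::runif(n_noise, 1, chroms$length_bp[nc] - 100),
                          block = "noise", is_noise = TRUE, copy = NA_integer_,
                          stringsAsFactors = FALSE)
      truth <- rbind(truth, noise)
    }

    ev <- ifelse(truth$is_noise,
                 10^stats::runif(nrow(truth), -6, -5),
                 10^stats::runif(nrow(truth), -9, log10(9e-6)))
    pid <- ifelse(truth$is_noise,
                  stats::runif(nrow(truth), 63, 80),
                  stats::runif(nrow(truth), 78, 99))
    minus <- stats::runif(nrow(truth)) < 0.5
    s1 <- round(truth$bp); s2 <- round(truth$bp) + 89
    matches <- data.frame(
      qseqid = truth$qseqid, sseqid = truth$chr,
      pident = round(pid, 2), length = 30L,
      mismatch = round(30 * (100 - pid) / 100), gapopen = 0L,
      qstart = 1L, qend = 90L,
      sstart = ifelse(minus, s2, s1), send = ifelse(minus, s1, s2),
      evalue = signif(ev, 3), bitscore = round(35 - 3 * log10(ev), 1),
      stringsAsFactors = FALSE)
    truth$position <- round(truth$bp)
    list(matches = matches,
         truth = truth[c("qseqid", "chr", "position", "is_noise", "copy", "block")],
         chromosome_lengths = chroms)
  })
}

#' Write matches in BLAST tabular format
#'
#' @param matches data frame with the 12 standard columns.
#' @param path output file.
#' @export
write_blast_tabular <- function(matches, path) {
  utils::write.table(format(matches[BLAST_COLS], trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
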