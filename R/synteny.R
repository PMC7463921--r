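# Macro-synteny filtering of translated-BLAST tabular hits of genetic-map
# marker tags against chromosome-level reference genomes, and dotplot
# coordinate preparation.

BLAST_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read 12-column BLAST tabular output (outfmt 6)
#'
#' Parses tab-separated hits, drops hits above the significance cut and hits
#' to subjects absent from the chromosome table (unanchored scaffolds), and
#' normalises reversed subject coordinates (minus-strand translated hits) to
#' `sstart <= send` with an `orientation` flag.
#'
#' @param path file path.
#' @param chromosome_lengths optional data frame with columns `name`,
#'   `length_bp`; required when `exclude_unanchored = TRUE`.
#' @param exclude_unanchored drop hits to subjects not in the chromosome
#'   table (default `TRUE` when a table is given).
#' @param max_evalue significance cut (default 1e-5; hits strictly above it
#'   are dropped).
#' @return data frame of matches; attribute `"dropped"` records per-stage
#'   drop counts.
#' @export
read_blast_tabular <- function(path, chromosome_lengths = NULL,
                               exclude_unanchored = !is.null(chromosome_lengths),
                               max_evalue = 1e-5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_bad("no hit rows in %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop_bad("malformed BLAST tabular row at line %d of %s (%d columns, expected 12)",
             bad, path, nf[bad])
  }
  m <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(m) <- BLAST_COLS
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(m[[cn]]))
    if (anyNA(v))
      stop_bad("non-numeric value in column %s at line %d of %s",
               cn, which(is.na(v))[1], path)
    m[[cn]] <- v
  }
  n0 <- nrow(m)
  keep <- m$evalue <= max_evalue
  n_evalue <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  n_unanchored <- 0L
  if (exclude_unanchored) {
    if (is.null(chromosome_lengths))
      stop_bad("chromosome_lengths required to exclude unanchored scaffolds")
    keep <- m$sseqid %in% chromosome_lengths$name
    n_unanchored <- sum(!keep)
    m <- m[keep, , drop = FALSE]
  }
  rev <- m$sstart > m$send
  tmp <- m$sstart[rev]; m$sstart[rev] <- m$send[rev]; m$send[rev] <- tmp
  m$orientation <- ifelse(rev, "-", "+")
  if (!is.null(chromosome_lengths)) {
    len <- chromosome_lengths$length_bp[match(m$sseqid, chromosome_lengths$name)]
    out_of_range <- !is.na(len) & (m$sstart < 1 | m$send > len)
    if (any(out_of_range))
      stop_bad("%d hit(s) extend beyond their chromosome length (first subject: %s)",
               sum(out_of_range), m$sseqid[which(out_of_range)[1]])
  }
  rownames(m) <- NULL
  attr(m, "dropped") <- list(parsed = n0, evalue = n_evalue,
                             unanchored = n_unanchored)
  m
}

# ranking used everywhere a "top" hit is selected
hit_order <- function(m) order(m$evalue, -m$bitscore, m$sseqid, m$qseqid)

#' Keep the top hit(s) per marker
#'
#' Without WGD mode, the single best hit per query marker is kept (lowest
#' e-value; ties by highest bitscore, then lexicographic chromosome). With
#' `wgd_mode` (for a target carrying a whole-genome duplication) the best
#' hit per (marker, chromosome) pair is selected first, then the best two of
#' those per marker — so a marker can retain at most two hits and never two
#' on the same chromosome.
#'
#' @param matches data frame from [read_blast_tabular()].
#' @param wgd_mode logical.
#' @return filtered data frame; attribute `"dropped"` counts removed rows.
#' @export
filter_top_hits <- function(matches, wgd_mode = FALSE) {
  n0 <- nrow(matches)
  m <- matches[hit_order(matches), , drop = FALSE]
  if (wgd_mode) {
    m <- m[!duplicated(paste(m$qseqid, m$sseqid, sep = "\r")), , drop = FALSE]
    keep <- stats::ave(seq_len(nrow(m)), m$qseqid, FUN = seq_along) <= 2L
    m <- m[keep, , drop = FALSE]
  } else {
    m <- m[!duplicated(m$qseqid), , drop = FALSE]
  }
  m <- m[order(match(rownames(m), rownames(matches))), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "dropped") <- n0 - nrow(m)
  m
}

#' Attach linkage-group positions to matches
#'
#' @param matches BLAST match data frame.
#' @param map_table data frame with `marker`, `group`, `position_cM`.
#' @return matches with `linkage_group` and `position_cM` columns; markers
#'   absent from the map are dropped (counted in attribute `"dropped"`).
#' @export
join_map_positions <- function(matches, map_table) {
  i <- match(matches$qseqid, map_table$marker)
  out <- matches[!is.na(i), , drop = FALSE]
  out$linkage_group <- map_table$group[i[!is.na(i)]]
  out$position_cM <- map_table$position_cM[i[!is.na(i)]]
  attr(out, "dropped") <- sum(is.na(i))
  out
}

#' Remove isolated marker matches
#'
#' Orders all matches by concatenated genomic position (natural chromosome
#' order, then subject midpoint, ties by marker id) and examines, for each
#' match, the window of five consecutive matches centred on it (truncated to
#' the available two neighbours per side at the list ends). A match is
#' removed iff no other match in its window shares its (linkage group,
#' chromosome) pairing. Flags are computed on the pre-removal list in a
#' single pass, so removal of one match never triggers removal of its
#' neighbours.
#'
#' @param matches data frame with `linkage_group`, `sseqid`, `sstart`,
#'   `send`, `qseqid`.
#' @return filtered data frame; attributes `"dropped"` (count) and
#'   `"removed"` (the removed rows).
#' @export
remove_isolated <- function(matches) {
  if (nrow(matches) < 5L) {
    warning("fewer than 5 matches: isolated-match filter not applied")
    attr(matches, "dropped") <- 0L
    return(matches)
  }
  chr_rank <- match(matches$sseqid, natural_sort(unique(matches$sseqid)))
  mid <- (matches$sstart + matches$send) / 2
  ord <- order(chr_rank, mid, matches$qseqid)
  pairing <- paste(matches$linkage_group, matches$sseqid, sep = "\r")[ord]
  n <- length(ord)
  isolated <- vapply(seq_len(n), function(i) {
    win <- max(1L, i - 2L):min(n, i + 2L)
    !any(pairing[setdiff(win, i)] == pairing[i])
  }, logical(1))
  removed <- matches[ord[isolated], , drop = FALSE]
  out <- matches[sort(ord[!isolated]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(isolated)
  attr(out, "removed") <- removed
  out
}

#' Concatenate per-chromosome and per-group coordinates for plotting
#'
#' Computes genome-wide x (chromosome offset + hit midpoint) and map-wide y
#' (linkage-group offset + cM position) for every match, with boundary ticks
#' for gridlines. Chromosomes are offset in natural-sort order; linkage
#' groups in the order given.
#'
#' @param matches filtered matches carrying `linkage_group`, `position_cM`.
#' @param chromosome_lengths data frame `name`, `length_bp`.
#' @param group_lengths data frame `group`, `length_cM`.
#' @return object of class `synteny_alignment`: list with `matches` (plus
#'   `x`, `y`), `chrom_offsets`, `group_offsets`.
#' @export
concatenate_coordinates <- function(matches, chromosome_lengths, group_lengths) {
  chroms <- natural_sort(chromosome_lengths$name)
  lens <- chromosome_lengths$length_bp[match(chroms, chromosome_lengths$name)]
  offs <- stats::setNames(cumsum(c(0, lens[-length(lens)])), chroms)
  unknown <- setdiff(unique(matches$sseqid), chroms)
  if (length(unknown) > 0)
    stop_bad("match references unknown chromosome(s): %s",
             paste(unknown, collapse = ", "))
  groups <- group_lengths$group
  glens <- group_lengths$length_cM
  goffs <- stats::setNames(cumsum(c(0, glens[-length(glens)])), groups)
  if (!all(matches$linkage_group %in% groups))
    stop_bad("match references unknown linkage group")
  matches$x <- offs[matches$sseqid] + (matches$sstart + matches$send) / 2
  matches$y <- goffs[matches$linkage_group] + matches$position_cM
  structure(list(matches = matches,
                 chrom_offsets = data.frame(name = chroms, offset = unname(offs),
                                            length_bp = lens,
                                            stringsAsFactors = FALSE),
                 group_offsets = data.frame(group = groups, offset = unname(goffs),
                                            length_cM = glens,
                                            stringsAsFactors = FALSE)),
            class = "synteny_alignment")
}

#' @export
print.synteny_alignment <- function(x, ...) {
  cat(sprintf("synteny_alignment: %d matches, %d chromosomes x %d linkage groups\n",
              nrow(x$matches), nrow(x$chrom_offsets), nrow(x$group_offsets)))
  invisible(x)
}

#' Write dotplot data and image
#'
#' Writes a gnuplot-compatible two-column data file (blank-line-separated
#' series per linkage-group x chromosome pairing, in the style of the
#' MUMmerplot configuration) and renders a raster dotplot with chromosome
#' and group gridlines using base graphics.
#'
#' @param alignment a [concatenate_coordinates()] result.
#' @param out_prefix path prefix; writes `<prefix>.dat` and `<prefix>.png`.
#' @param title plot title.
#' @return invisibly, the two file paths.
#' @export
write_dotplot <- function(alignment, out_prefix, title = "map vs genome") {
  stopifnot(inherits(alignment, "synteny_alignment"))
  m <- alignment$matches
  if (nrow(m) == 0L) stop_bad("empty alignment: nothing to plot")
  key <- paste(m$linkage_group, m$sseqid, sep = " x ")
  dat <- paste0(out_prefix, ".dat")
  con <- file(dat, "w")
  for (k in unique(key)) {
    writeLines(sprintf("# %s", k), con)
    sub <- m[key == k, , drop = FALSE]
    writeLines(sprintf("%.1f\t%.4f", sub$x, sub$y), con)
    writeLines("", con)
  }
  close(con)
  png_path <- paste0(out_prefix, ".png")
  grDevices::png(png_path, width = 900, height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(m$x, m$y, pch = 20, cex = 0.5, col = "#00000088",
                 xlab = "genome position (bp, concatenated)",
                 ylab = "map position (cM, concatenated)", main = title)
  graphics::abline(v = alignment$chrom_offsets$offset[-1], col = "grey70")
  graphics::abline(h = alignment$group_offsets$offset[-1], col = "grey70")
  invisible(c(dat, png_path))
}
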