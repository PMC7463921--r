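# Ks-distribution construction: top-match gene-pair lists, kernel-density
# peak detection, and the Ks-peak distance matrix over WGD replicate leaves.

#' Build top-match gene-pair lists for a species pair
#'
#' From an all-by-all hit table containing both query directions, keeps
#' significant hits (`evalue <= 1e-5`), drops self-hits (a gene matching
#' itself) for self-self species pairs, applies the identity filter
#' (`pident > 90`), extracts the lowest-e-value match per query gene (ties by
#' bitscore, then subject id), and unions the two directions into one list
#' of unordered pairs.
#'
#' @param hits data frame with at least `qseqid`, `sseqid`, `pident`,
#'   `evalue`, `bitscore`.
#' @param self logical: is this a species queried against itself?
#' @param min_identity identity threshold, percent (strict `>`).
#' @param max_evalue significance cut.
#' @return data frame with `gene_a`, `gene_b` (sorted within pair),
#'   `pident`, `evalue`.
#' @export
build_top_match_lists <- function(hits, self = FALSE, min_identity = 90,
                                  max_evalue = 1e-5) {
  if (nrow(hits) == 0L) stop_bad("empty hit table")
  m <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (self) m <- m[m$qseqid != m$sseqid, , drop = FALSE]
  m <- m[m$pident > min_identity, , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      pident = numeric(), evalue = numeric()))
  m <- m[order(m$evalue, -m$bitscore, m$sseqid), , drop = FALSE]
  m <- m[!duplicated(m$qseqid), , drop = FALSE]
  a <- pmin(m$qseqid, m$sseqid); b <- pmax(m$qseqid, m$sseqid)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(gene_a = a[keep], gene_b = b[keep],
             pident = m$pident[keep], evalue = m$evalue[keep],
             stringsAsFactors = FALSE)
}

#' Detect peaks of a Ks distribution
#'
#' Gaussian kernel density (Silverman bandwidth by default), evaluated over
#' `[0, range]` on a 0.001-step grid; every local maximum is reported, with
#' the global one flagged, so a multi-modal distribution (speciation peak
#' plus WGD paralog peak) exposes all candidate peaks for the user to choose
#' from.
#'
#' By default the kernel is placed on log-Ks support and the density mapped
#' back (\eqn{f_X(x) = f_{\log}( \log x)/x}): Ks distributions are strongly
#' right-skewed, and a linear-support kernel smears the shoulder into the
#' mode, biasing peaks upward by several percent.
#'
#' @param ks numeric vector of Ks values.
#' @param range upper end of the scanned support (default 2).
#' @param bandwidth kernel bandwidth; default Silverman's rule of thumb on
#'   the (log) support.
#' @param log_support place the kernel on log(Ks) (default `TRUE`).
#' @return data frame with `ks` (peak location), `density`, `global`.
#' @export
detect_ks_peak <- function(ks, range = 2, bandwidth = NULL,
                           log_support = TRUE) {
  x <- ks[is.finite(ks) & ks >= 0 & ks <= range]
  if (length(x) < 50L)
    stop_bad("need >= 50 finite Ks values in [0, %g]; got %d", range, length(x))
  grid <- seq(0, range, by = 0.001)
  if (stats::sd(x) < 1e-12) {   # degenerate sample: the point mass is the peak
    return(data.frame(ks = grid[which.min(abs(grid - x[1]))],
                      density = Inf, global = TRUE))
  }
  if (log_support && all(x > 0)) {
    lx <- log(x)
    bw <- bandwidth %||% stats::bw.nrd0(lx)
    dl <- stats::density(lx, bw = bw, from = log(max(min(grid[-1]), 1e-4)),
                         to = log(range), n = 4096)
    y <- c(0, stats::approx(dl$x, dl$y, xout = log(grid[-1]), rule = 2)$y / grid[-1])
  } else {
    bw <- bandwidth %||% stats::bw.nrd0(x)
    y <- stats::density(x, bw = bw, from = 0, to = range, n = length(grid))$y
  }
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  if (!any(is_max)) is_max[which.max(y)] <- TRUE
  out <- data.frame(ks = grid[is_max], density = y[is_max])
  out$global <- out$density == max(out$density)
  out <- out[order(-out$density), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the Ks-peak distance matrix over WGD replicate leaves
#'
#' Every species contributes two replicate leaves representing the gene
#' populations descending from the two halves of its most recent WGD.
#' Species whose most recent WGD is the shared papilionoid one place one
#' replicate in each papilionoid half; a species with a more recent
#' lineage-specific WGD (e.g. Glycine) contributes the two halves of that
#' WGD, which both sit inside one papilionoid half. Entries: a species' own
#' replicates are separated by its self-peak; cross-species leaves in the
#' same papilionoid half by that pair's speciation peak (assumed
#' representative of both halves); leaves on opposite papilionoid halves by
#' the papilionoid-WGD peak (cross-species paralogs). With exact peaks the
#' matrix is exactly ultrametric.
#'
#' @param cross_peaks named numeric vector of speciation Ks peaks keyed
#'   `"A|B"` (sorted species names).
#' @param self_peaks named numeric vector of self-pair Ks peaks per species.
#' @param recent_wgd species whose most recent WGD is lineage-specific.
#' @param papilionoid_peak Ks peak of the shared papilionoid WGD; default:
#'   mean self-peak of the species not in `recent_wgd`.
#' @return object of class `ks_peak_matrix`: list with `matrix` (symmetric,
#'   zero diagonal), `leaves` (data frame `leaf`, `species`, `half`) and
#'   `papilionoid_peak`.
#' @export
build_peak_matrix <- function(cross_peaks, self_peaks,
                              recent_wgd = character(),
                              papilionoid_peak = NULL) {
  species <- sort(names(self_peaks))
  need <- outer(species, species, function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|"))
  need <- setdiff(need[upper.tri(need)], names(cross_peaks))
  if (length(need) > 0)
    stop_bad("missing cross-species peak(s): %s", paste(need, collapse = ", "))
  base_sp <- setdiff(species, recent_wgd)
  if (is.null(papilionoid_peak)) {
    if (length(base_sp) == 0)
      stop_bad("papilionoid_peak must be given when every species has a recent WGD")
    papilionoid_peak <- mean(self_peaks[base_sp])
  }
  leaves <- do.call(rbind, lapply(species, function(sp) {
    if (sp %in% recent_wgd)
      data.frame(leaf = paste0(sp, c("_1", "_2")), species = sp,
                 half = c("A", "A"), stringsAsFactors = FALSE)
    else
      data.frame(leaf = paste0(sp, c("_A", "_B")), species = sp,
                 half = c("A", "B"), stringsAsFactors = FALSE)
  }))
  n <- nrow(leaves)
  M <- matrix(0, n, n, dimnames = list(leaves$leaf, leaves$leaf))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    si <- leaves$species[i]; sj <- leaves$species[j]
    M[i, j] <- M[j, i] <-
      if (si == sj) self_peaks[[si]]
      else if (leaves$half[i] != leaves$half[j]) papilionoid_peak
      else cross_peaks[[paste(min(si, sj), max(si, sj), sep = "|")]]
  }
  structure(list(matrix = M, leaves = leaves,
                 papilionoid_peak = papilionoid_peak),
            class = "ks_peak_matrix")
}

#' @export
print.ks_peak_matrix <- function(x, ...) {
  cat(sprintf("ks_peak_matrix: %d leaves (%d species), papilionoid peak %.3f\n",
              nrow(x$leaves), length(unique(x$leaves$species)),
              x$papilionoid_peak))
  invisible(x)
}
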