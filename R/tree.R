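# Topology inference, ultrametric non-negative least-squares node heights,
# and calibration of node ages at the papilionoid WGD.

#' Infer the tree topology from a Ks-peak distance matrix
#'
#' Neighbor-joining (the default) or UPGMA on the symmetric peak matrix,
#' rooted on the branch representing the papilionoid WGD — the split
#' between the two papilionoid half-clades. When `x` is a
#' [build_peak_matrix()] result the half labels identify that branch;
#' otherwise pass `outgroup` explicitly.
#'
#' @param x a `ks_peak_matrix` or a symmetric distance matrix.
#' @param method `"nj"` or `"upgma"`.
#' @param outgroup leaf labels of one papilionoid half (used to root when
#'   half labels are unavailable; ignored for UPGMA, which is rooted by
#'   construction).
#' @param tol symmetry tolerance.
#' @return a rooted `ape::phylo`.
#' @export
infer_topology <- function(x, method = c("nj", "upgma"), outgroup = NULL,
                           tol = 1e-8) {
  method <- match.arg(method)
  M <- if (inherits(x, "ks_peak_matrix")) x$matrix else as.matrix(x)
  if (nrow(M) < 3L) stop_bad("need at least 3 leaves")
  if (max(abs(M - t(M))) > tol) stop_bad("matrix is not symmetric")
  if (is.null(outgroup) && inherits(x, "ks_peak_matrix")) {
    halves <- x$leaves$half
    if (length(unique(halves)) == 2L) {
      # root between the halves; the smaller side is the outgroup
      sides <- split(x$leaves$leaf, halves)
      outgroup <- sides[[which.min(lengths(sides))]]
    }
  }
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(M), method = "average")
    phy <- ape::as.phylo(hc)
    return(phy)
  }
  phy <- ape::nj(M)
  if (!is.null(outgroup)) {
    phy <- tryCatch(
      ape::root(phy, outgroup = outgroup, resolve.root = TRUE),
      error = function(e)
        stop_bad("cannot root on the requested split (%s)", conditionMessage(e)))
  } else {
    # fall back: root on the longest internal branch
    internal <- which(phy$edge[, 2] > length(phy$tip.label))
    if (length(internal) > 0) {
      e <- internal[which.max(phy$edge.length[internal])]
      below <- ape::extract.clade(phy, phy$edge[e, 2])$tip.label
      phy <- ape::root(phy, outgroup = below, resolve.root = TRUE)
    }
  }
  phy
}

# Leaf pairs grouped by their MRCA node, with mean half-distance and weight.
mrca_pair_stats <- function(phy, M) {
  tips <- phy$tip.label
  if (!setequal(tips, rownames(M)))
    stop_bad("matrix leaves do not match tree tips")
  mr <- ape::mrca(phy)
  vals <- list()
  for (i in seq_along(tips)) for (j in seq_along(tips)) {
    if (i >= j) next
    v <- mr[tips[i], tips[j]]
    key <- as.character(v)
    vals[[key]] <- c(vals[[key]], M[tips[i], tips[j]])
  }
  data.frame(node = as.integer(names(vals)),
             mean_half = vapply(vals, mean, numeric(1)) / 2,
             weight = lengths(vals))
}

#' Ultrametric non-negative least-squares node heights
#'
#' Fits node heights h minimising \eqn{\sum_{i<j} (d_{ij} - 2 h_{MRCA(i,j)})^2}
#' subject to \eqn{h \ge 0} and \eqn{h(parent) \ge h(child)} on a fixed
#' rooted topology. Because each leaf pair involves exactly one node, the
#' problem is a weighted isotonic regression on the tree order of the
#' internal nodes and is solved exactly by bottom-up violator pooling.
#'
#' @param phy rooted `ape::phylo`.
#' @param M symmetric leaf distance matrix (row/col names = tip labels).
#' @return list with `heights` (named by internal node number), `residual`
#'   (root of the summed squared pair residuals), and `fitted` (the implied
#'   ultrametric pair distances).
#' @export
fit_ultrametric_nnls <- function(phy, M) {
  if (inherits(M, "ks_peak_matrix")) M <- M$matrix
  if (is.null(phy$edge) || !ape::is.rooted(phy))
    stop_bad("topology must be a rooted phylo tree")
  st <- mrca_pair_stats(phy, M)
  ntip <- length(phy$tip.label)
  nodes <- sort(st$node)
  val <- stats::setNames(st$mean_half[match(nodes, st$node)], nodes)
  wt <- stats::setNames(as.numeric(st$weight[match(nodes, st$node)]), nodes)
  parent_of <- stats::setNames(phy$edge[, 1], phy$edge[, 2])

  # blocks: value, weight, members, pending = list of child blocks hanging
  # below that may still violate if this block's value drops
  make_block <- function(v) list(value = val[[as.character(v)]],
                                 weight = wt[[as.character(v)]],
                                 members = v, pending = list())
  absorb <- function(block) {
    repeat {
      if (length(block$pending) == 0L) break
      pv <- vapply(block$pending, `[[`, numeric(1), "value")
      k <- which.max(pv)
      if (pv[k] <= block$value + 1e-12) break
      sub <- block$pending[[k]]
      tot <- block$weight + sub$weight
      block$value <- (block$value * block$weight + sub$value * sub$weight) / tot
      block$weight <- tot
      block$members <- c(block$members, sub$members)
      block$pending <- c(block$pending[-k], sub$pending)
    }
    block
  }
  # postorder over internal nodes (children before parents)
  po <- unique(ape::reorder.phylo(phy, "postorder")$edge[, 1])
  if (!all(po %in% nodes))
    stop_bad("internal node without any leaf pair: topology/matrix mismatch")
  done <- list()   # node -> block for the top block of its subtree
  for (v in po) {
    blk <- make_block(v)
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    for (k in kids[kids > ntip]) {
      kb <- done[[as.character(k)]]
      if (!is.null(kb)) blk$pending <- c(blk$pending, list(kb))
    }
    done[[as.character(v)]] <- absorb(blk)
  }
  root <- ntip + 1L
  flatten <- function(block, acc) {
    for (m in block$members) acc[[as.character(m)]] <- max(block$value, 0)
    for (p in block$pending) acc <- flatten(p, acc)
    acc
  }
  hts <- flatten(done[[as.character(root)]], list())
  heights <- stats::setNames(unlist(hts), names(hts))
  heights <- heights[order(as.integer(names(heights)))]

  tips <- phy$tip.label
  mr <- ape::mrca(phy)
  fitted <- M * 0
  for (i in seq_along(tips)) for (j in seq_along(tips)) if (i != j)
    fitted[tips[i], tips[j]] <- 2 * heights[[as.character(mr[tips[i], tips[j]])]]
  resid <- sqrt(sum(((M - fitted)[upper.tri(M)])^2))
  list(heights = heights, residual = resid, fitted = fitted)
}

#' Calibrate node ages against the root
#'
#' Scales fitted node heights linearly so that the root — the papilionoid
#' WGD — sits at `root_age_mya` (56.5 MYA by default); leaves are at 0.
#'
#' @param phy rooted `ape::phylo`.
#' @param heights named node heights from [fit_ultrametric_nnls()].
#' @param root_age_mya calibration age of the deepest node.
#' @return object of class `dated_tree`: list with `tree` (branch lengths in
#'   MYA), `ages` (named by internal node number), `heights`, `root_age`.
#' @export
calibrate_ages <- function(phy, heights, root_age_mya = 56.5) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  h_root <- heights[[as.character(root)]]
  if (!is.finite(h_root) || h_root <= 0) stop_bad("zero root height: cannot calibrate")
  ages <- vapply(heights, function(h) root_age_mya * h / h_root, numeric(1))
  age_of <- function(v) if (v <= ntip) 0 else ages[[as.character(v)]]
  phy$edge.length <- vapply(seq_len(nrow(phy$edge)), function(e)
    age_of(phy$edge[e, 1]) - age_of(phy$edge[e, 2]), numeric(1))
  structure(list(tree = phy, ages = ages, heights = heights,
                 root_age = root_age_mya),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("dated_tree: %d leaves, root (papilionoid WGD) at %.1f MYA\n",
              length(x$tree$tip.label), x$root_age))
  invisible(x)
}

#' Divergence age between two species in a dated replicate-leaf tree
#'
#' The speciation age is the age of the shallowest MRCA over the replicate
#' leaves of the two species (replicates in the same WGD half coalesce at
#' the speciation node; cross-half pairs at the papilionoid WGD).
#'
#' @param dated a [calibrate_ages()] result whose tips are replicate leaves
#'   named `<species>_<half>`.
#' @param sp_a,sp_b species names.
#' @return age in MYA.
#' @export
divergence_age <- function(dated, sp_a, sp_b) {
  phy <- dated$tree
  la <- grep(paste0("^", sp_a, "_"), phy$tip.label, value = TRUE)
  lb <- grep(paste0("^", sp_b, "_"), phy$tip.label, value = TRUE)
  if (length(la) == 0 || length(lb) == 0) stop_bad("species not found in tree")
  min(vapply(la, function(x) vapply(lb, function(y) {
    v <- ape::getMRCA(phy, c(x, y))
    dated$ages[[as.character(v)]]
  }, numeric(1)), numeric(length(lb))))
}

#' @rdname divergence_age
#' @param sp species name; returns the age of its most recent WGD (the MRCA
#'   of its two replicate leaves).
#' @export
wgd_age <- function(dated, sp) {
  phy <- dated$tree
  l <- grep(paste0("^", sp, "_"), phy$tip.label, value = TRUE)
  if (length(l) != 2L) stop_bad("species %s does not have two replicate leaves", sp)
  dated$ages[[as.character(ape::getMRCA(phy, l))]]
}

#' End-to-end Ks dating
#'
#' From per-species-pair Ks samples to a calibrated ultrametric tree:
#' detects the global Ks peak of every pair, assembles the replicate-leaf
#' peak matrix, infers the topology, fits ultrametric NNLS heights and
#' calibrates the root at `root_age_mya`.
#'
#' @param samples named list of Ks vectors keyed `"A|B"` (see
#'   [simulate_ks_samples()]).
#' @param recent_wgd species whose most recent WGD is lineage-specific.
#' @param root_age_mya calibration age (default 56.5).
#' @param method `"nj"` or `"upgma"`.
#' @param range,bandwidth passed to [detect_ks_peak()].
#' @return list with `peaks`, `peak_matrix`, `tree` (topology), `fit`,
#'   `dated` (a `dated_tree`).
#' @export
run_ks_dating <- function(samples, recent_wgd = character(),
                          root_age_mya = 56.5, method = "nj",
                          range = 2, bandwidth = NULL) {
  keys <- names(samples)
  sp <- strsplit(keys, "|", fixed = TRUE)
  peak1 <- vapply(samples, function(x) {
    p <- detect_ks_peak(x, range = range, bandwidth = bandwidth)
    p$ks[p$global][1]
  }, numeric(1))
  is_self <- vapply(sp, function(p) p[1] == p[2], logical(1))
  self_peaks <- stats::setNames(peak1[is_self],
                                vapply(sp[is_self], `[`, character(1), 1))
  cross_peaks <- peak1[!is_self]
  pm <- build_peak_matrix(cross_peaks, self_peaks, recent_wgd = recent_wgd)
  phy <- infer_topology(pm, method = method)
  fit <- fit_ultrametric_nnls(phy, pm$matrix)
  dated <- calibrate_ages(phy, fit$heights, root_age_mya)
  list(peaks = peak1, peak_matrix = pm, tree = phy, fit = fit, dated = dated)
}
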