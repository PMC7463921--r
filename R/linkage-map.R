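# Linkage-map construction: grouping, redundant binning, skeleton ordering
# with jackknife stability, marker attachment and Table-style summaries.

#' Cluster markers into linkage groups
#'
#' Single-linkage transitive closure over pairs linked at `rf <= threshold`
#' and `LOD >= min_lod`, applied at increasing rf thresholds: groups formed
#' at the lowest threshold are carried forward, and groups that remain
#' separate are re-clustered at the next threshold, stopping at the last.
#' Groups smaller than `min_size` are reported as unplaced.
#'
#' @param rf,lod square matrices from [rf_matrix()].
#' @param thresholds ascending rf thresholds (default 0.10, 0.15, 0.20).
#' @param min_lod LOD floor for accepting linkage (default 3).
#' @param min_size smallest group reported (default 4).
#' @param rf_up optional matrix of likelihood-interval upper bounds (from
#'   [rf_matrix()]). When given, a pair only counts as linked at a threshold
#'   if the whole interval sits below it: single linkage merges groups on a
#'   single edge, and the one class of pairs whose point estimates collapse
#'   spuriously — dominant markers in repulsion — is exactly the class with
#'   wide intervals.
#' @return list with `groups` (list of marker-id vectors, largest first) and
#'   `unplaced` (ids).
#' @export
cluster_markers <- function(rf, lod, thresholds = c(0.10, 0.15, 0.20),
                            min_lod = 3, min_size = 4, rf_up = NULL) {
  m <- ncol(rf)
  if (m == 0L) stop_bad("empty rf matrix")
  if (is.null(rf_up)) rf_up <- rf
  ids <- colnames(rf)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (thr in sort(thresholds)) {
    edges <- which(rf <= thr & rf_up <= thr & lod >= min_lod & upper.tri(rf),
                   arr.ind = TRUE)
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  grp <- split(ids, comp)
  sizes <- lengths(grp)
  groups <- grp[sizes >= min_size]
  groups <- groups[order(-lengths(groups),
                         vapply(groups, min, character(1)))]
  names(groups) <- NULL
  list(groups = groups, unplaced = unlist(grp[sizes < min_size], use.names = FALSE) %||% character(0))
}

#' Bin markers with redundant segregation patterns
#'
#' Markers of the same score type whose non-missing calls never conflict
#' (identical segregation, missing treated as a wildcard) share a bin; the
#' member with the fewest missing calls (ties broken by id) represents the
#' bin in ordering.
#'
#' @param geno phased integer matrix (individuals x markers of one linkage
#'   group).
#' @param scores score type per marker.
#' @return list with `representatives` (ids) and `bins` (named list,
#'   representative -> all member ids including itself).
#' @export
bin_redundant <- function(geno, scores) {
  ids <- colnames(geno)
  nmiss <- colSums(is.na(geno))
  ord <- order(nmiss, ids)
  reps <- integer(0)
  assign <- integer(length(ids))
  for (j in ord) {
    placed <- FALSE
    for (r in reps) {
      if (scores[r] != scores[j]) next
      a <- geno[, r]; b <- geno[, j]
      both <- !is.na(a) & !is.na(b)
      if (any(both) && all(a[both] == b[both])) {
        assign[j] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, j); assign[j] <- j }
  }
  bins <- split(ids, ids[assign])
  bins <- bins[ids[sort(reps)]]   # stable: bins keyed in input column order
  list(representatives = ids[sort(reps)], bins = bins)
}

# Total adjacent map length of an order (capped Kosambi distances).
order_cost <- function(D, ord) sum(D[cbind(ord[-length(ord)], ord[-1])])

# Greedy double-ended nearest-neighbour chain seeded at a codominant marker.
greedy_chain <- function(D, co_mask) {
  n <- nrow(D)
  seed_pool <- if (any(co_mask)) which(co_mask) else seq_len(n)
  # likely terminal marker: largest mean distance to the rest
  seed <- seed_pool[which.max(rowMeans(D[seed_pool, , drop = FALSE]))]
  chain <- c(seed)
  left <- seed; right <- seed
  unused <- setdiff(seq_len(n), seed)
  while (length(unused) > 0L) {
    dl <- D[left, unused]; dr <- D[right, unused]
    if (min(dl) <= min(dr)) {
      k <- unused[which.min(dl)]; chain <- c(k, chain); left <- k
    } else {
      k <- unused[which.min(dr)]; chain <- c(chain, k); right <- k
    }
    unused <- setdiff(unused, k)
  }
  chain
}

# Seriation: global order from the first principal coordinate of the
# distance matrix (robust to pairwise noise well below marker spacing),
# polished by *windowed* 2-opt reversals and single-marker relocations that
# minimise total adjacent length. The window keeps the polish local: at
# marker densities below the rf resolution the adjacent-length objective
# cannot distinguish the true order from noise-chasing zigzags, so global
# rearrangements are left to the eigenvector and only local errors are
# repaired. Falls back to a greedy nearest-neighbour chain (seeded at a
# codominant marker) if the spectral embedding is degenerate.
seriate_order <- function(D, co_mask, window = 10L) {
  n <- nrow(D)
  if (n <= 2L) return(seq_len(n))
  chain <- tryCatch({
    ax <- stats::cmdscale(stats::as.dist(D), k = 1)
    if (max(abs(ax)) < 1e-12) greedy_chain(D, co_mask) else order(ax[, 1])
  }, error = function(e) greedy_chain(D, co_mask))
  improve <- TRUE; guard <- 0L
  while (improve && guard < 60L) {
    improve <- FALSE; guard <- guard + 1L
    # windowed 2-opt: reverse segment [i..j], j - i < window
    for (i in seq_len(n - 1L)) {
      jset <- (i + 1L):min(n, i + window)
      li <- if (i > 1L) chain[i - 1L] else 0L
      d_li_i <- if (li > 0L) D[li, chain[i]] else 0
      add1 <- if (li > 0L) D[li, chain[jset]] else 0
      rj <- ifelse(jset < n, chain[pmin(jset + 1L, n)], 0L)
      d_j_rj <- ifelse(rj > 0L, D[cbind(chain[jset], rj)], 0)
      add2 <- ifelse(rj > 0L, D[cbind(rep(chain[i], length(jset)), rj)], 0)
      delta <- add1 + add2 - d_li_i - d_j_rj
      best <- which.min(delta)
      if (delta[best] < -1e-9) {
        j <- jset[best]
        chain[i:j] <- chain[j:i]
        improve <- TRUE
      }
    }
  }
  # block relocation (Or-opt) sweeps: move a segment of up to `block_max`
  # markers (optionally reversed) to any slot; fixes block transpositions
  # that windowed reversals cannot reach. Full-length prefix/suffix
  # reversals are deliberately absent: they change a single edge cost, so
  # one noisy distant-pair estimate can trigger a global reversal that
  # scrambles an order the objective cannot actually resolve.
  block_max <- min(12L, n - 1L)
  improve <- TRUE; guard <- 0L
  while (improve && guard < 20L) {
    improve <- FALSE; guard <- guard + 1L
    for (L in 1:block_max) {
      for (i in seq_len(n - L + 1L)) {
        j <- i + L - 1L
        l <- if (i > 1L) chain[i - 1L] else 0L
        r <- if (j < n) chain[j + 1L] else 0L
        head_ <- chain[i]; tail_ <- chain[j]
        gain <- (if (l > 0L) D[l, head_] else 0) +
          (if (r > 0L) D[tail_, r] else 0) -
          (if (l > 0L && r > 0L) D[l, r] else 0)
        rest <- chain[-(i:j)]
        nr <- length(rest)
        a <- c(0L, rest); b <- c(rest, 0L)
        slots <- seq_len(nr + 1L)   # full range: folds can sit far away
        as_ <- a[slots]; bs_ <- b[slots]
        da <- db <- dar <- dbr <- dab <- numeric(length(slots))
        da[as_ > 0L] <- D[cbind(as_[as_ > 0L], head_)]
        db[bs_ > 0L] <- D[cbind(tail_, bs_[bs_ > 0L])]
        dar[as_ > 0L] <- D[cbind(as_[as_ > 0L], tail_)]  # reversed insertion
        dbr[bs_ > 0L] <- D[cbind(head_, bs_[bs_ > 0L])]
        in_ <- as_ > 0L & bs_ > 0L
        dab[in_] <- D[cbind(as_[in_], bs_[in_])]
        d_fwd <- da + db - dab - gain
        d_rev <- dar + dbr - dab - gain
        d_fwd[slots == i] <- 0  # reinsertion in place
        kf <- which.min(d_fwd); kr <- which.min(d_rev)
        if (min(d_fwd[kf], d_rev[kr]) < -1e-9) {
          seg <- chain[i:j]
          if (d_rev[kr] < d_fwd[kf]) {
            chain <- append(rest, rev(seg), after = slots[kr] - 1L)
          } else {
            chain <- append(rest, seg, after = slots[kf] - 1L)
          }
          improve <- TRUE
        }
      }
    }
  }
  chain
}

#' Order the skeleton of one linkage group with jackknife stability
#'
#' Orders bin representatives by greedy rf-seriation (codominant markers are
#' the preferred seeds) with 2-opt refinement, minimising total adjacent
#' Kosambi length. Order stability is then probed by reordering on
#' `n_jackknife` leave-10%-out individual subsets; a marker's stability is
#' the fraction of resamples in which its full-data neighbours (one at the
#' ends) are still its neighbours. Markers below `stability_threshold` are
#' removed and the remainder reordered once.
#'
#' @param geno phased integer matrix (individuals x representative markers).
#' @param scores score type per marker.
#' @param n_jackknife number of jackknife resamples (default 30).
#' @param stability_threshold minimum neighbour-preservation fraction
#'   (default 0.8).
#' @param neighbor_window a reference neighbour counts as preserved when it
#'   sits within this many positions of the marker in the resampled order
#'   (default 5; 1 = strict adjacency). At marker spacings below the rf
#'   resolution, adjacent markers swap freely between resamples without the
#'   order being wrong at any meaningful scale; the window keeps the
#'   stability score sensitive to genuine placement instability only.
#' @param seed integer seed for the resamples.
#' @param rf_cap rf above which distances are capped before seriation.
#' @return list with `order` (skeleton ids in map order), `removed`
#'   (destabilising ids, to be attached later), `stability` (named vector).
#' @export
order_skeleton <- function(geno, scores, n_jackknife = 30,
                           stability_threshold = 0.8, neighbor_window = 5L,
                           seed = 1L, rf_cap = 0.45) {
  ids <- colnames(geno)
  n <- length(ids)
  if (n < 3L)
    return(list(order = ids, removed = character(0),
                stability = stats::setNames(rep(1, n), ids)))
  co_mask <- scores == "co"
  dist_of <- function(g) {
    est <- rf_matrix(g, scores)
    # order on the conservative end of the likelihood interval: point
    # estimates from weakly informative pairs (dominant repulsion) otherwise
    # masquerade as tight linkage and derail the seriation
    r <- pmin(est$rf_up, rf_cap)
    r[est$n < 10] <- rf_cap
    kosambi(r)
  }
  D <- dist_of(geno)
  ref <- seriate_order(D, co_mask)
  neigh <- function(ord) {   # reference neighbours, indexed by marker
    lapply(seq_along(ord), function(k) {
      ord[c(if (k > 1L) k - 1L, if (k < length(ord)) k + 1L)]
    })[order(ord)]
  }
  ref_nb <- neigh(ref)
  stab <- rep(0, n)
  nind <- nrow(geno)
  drop_n <- max(1L, floor(0.1 * nind))
  with_seed(derive_seed(seed, "jackknife"), {
    for (b in seq_len(n_jackknife)) {
      keep <- sort(sample(nind, nind - drop_n))
      Db <- dist_of(geno[keep, , drop = FALSE])
      ob <- seriate_order(Db, co_mask)
      pos_b <- order(ob)   # position of each marker in the resample order
      stab <- stab + vapply(seq_len(n), function(j)
        all(abs(pos_b[ref_nb[[j]]] - pos_b[j]) <= neighbor_window), numeric(1))
    }
  })
  stab <- stab / n_jackknife
  names(stab) <- ids
  keep <- stab >= stability_threshold
  if (sum(keep) < 3L)  # always retain a minimal skeleton
    keep <- rank(-stab, ties.method = "first") <= 3L
  final <- if (all(keep)) ref else {
    sub <- which(keep)
    sub[seriate_order(D[sub, sub, drop = FALSE], co_mask[sub])]
  }
  ord_ids <- ids[final]
  if (ord_ids[1] > ord_ids[length(ord_ids)]) ord_ids <- rev(ord_ids)
  list(order = ord_ids, removed = ids[!keep], stability = stab)
}

#' Attach a marker to its most likely skeleton interval
#'
#' Assigns each marker to the interval whose flanking skeleton markers
#' jointly minimise the summed recombination fraction; terminal placements
#' are flanked by a single marker. Markers with rf above `max_rf` to every
#' skeleton marker stay unplaced.
#'
#' @param rf_to_skeleton numeric vector: rf of the marker to each skeleton
#'   marker, in skeleton order.
#' @param skeleton_ids skeleton marker ids in map order.
#' @param max_rf linkage ceiling (default 0.3).
#' @return `NULL` if unplaced, else list with `left`, `right` (flanking
#'   skeleton ids; equal at a terminal placement) and `rf_sum`.
#' @export
attach_interval <- function(rf_to_skeleton, skeleton_ids, max_rf = 0.3) {
  k <- length(skeleton_ids)
  stopifnot(length(rf_to_skeleton) == k)
  if (min(rf_to_skeleton) > max_rf) return(NULL)
  if (k == 1L)
    return(list(left = skeleton_ids[1], right = skeleton_ids[1],
                rf_sum = 2 * rf_to_skeleton[1]))
  scores <- c(2 * rf_to_skeleton[1],                       # beyond first
              rf_to_skeleton[-k] + rf_to_skeleton[-1],     # interior
              2 * rf_to_skeleton[k])                       # beyond last
  best <- which.min(scores)
  if (best == 1L)
    list(left = skeleton_ids[1], right = skeleton_ids[1], rf_sum = scores[1])
  else if (best == k + 1L)
    list(left = skeleton_ids[k], right = skeleton_ids[k], rf_sum = scores[k + 1])
  else
    list(left = skeleton_ids[best - 1L], right = skeleton_ids[best],
         rf_sum = scores[best])
}

#' Build the full linkage map from phased genotypes
#'
#' Runs the complete mapping chain: pairwise rf estimation, iterative
#' linkage grouping, per-group redundant binning, skeleton ordering with
#' jackknife stability, Kosambi positions accumulated over adjacent skeleton
#' intervals (refined by continuous ML), resolution of dual-retained phases
#' against the skeleton, and attachment of removed and dual markers to
#' intervals.
#'
#' @param phased a [phase_genotypes()] result.
#' @param rf_thresholds,min_lod,min_group_size passed to [cluster_markers()].
#' @param n_jackknife,stability_threshold passed to [order_skeleton()].
#' @param attach_max_rf linkage ceiling for attachment (default 0.3).
#' @param seed integer seed (jackknife resampling).
#' @return object of class `genetic_map`: list with `groups` (each:
#'   `name`, `skeleton` data frame of `marker`/`position_cM`, `bins`,
#'   `attached` data frame), `classes` (data frame: `marker`, `group`,
#'   `class` in skeleton/redundant/attached/unplaced), `unplaced` ids.
#' @export
build_linkage_map <- function(phased,
                              rf_thresholds = c(0.10, 0.15, 0.20),
                              min_lod = 3, min_group_size = 4,
                              n_jackknife = 30, stability_threshold = 0.8,
                              attach_max_rf = 0.3, seed = 1L) {
  stopifnot(inherits(phased, "phased_genotypes"))
  mk <- phased$markers
  resolved <- mk$id[mk$phase_state == "resolved"]
  dual <- mk$id[mk$phase_state == "dual-retained"]
  geno <- phased$geno[, resolved, drop = FALSE]
  scores <- stats::setNames(mk$score, mk$id)

  est <- rf_matrix(geno, scores[resolved])
  cl <- cluster_markers(est$rf, est$lod, rf_thresholds, min_lod, min_group_size,
                        rf_up = est$rf_up)

  classes <- data.frame(marker = mk$id, group = NA_character_,
                        class = "unplaced", stringsAsFactors = FALSE)
  rownames(classes) <- mk$id
  groups <- list()
  for (gi in seq_along(cl$groups)) {
    gids <- cl$groups[[gi]]
    gname <- sprintf("LG%02d", gi)
    sub <- geno[, gids, drop = FALSE]
    bn <- bin_redundant(sub, scores[gids])
    reps <- bn$representatives
    osk <- order_skeleton(sub[, reps, drop = FALSE], scores[reps],
                          n_jackknife = n_jackknife,
                          stability_threshold = stability_threshold,
                          seed = seed + gi)
    skel <- osk$order
    # refined adjacent distances by continuous ML
    pos <- c(0, cumsum(vapply(seq_len(length(skel) - 1L), function(i) {
      r <- estimate_rf(sub[, skel[i]], sub[, skel[i + 1L]],
                       scores[skel[i]], scores[skel[i + 1L]])$rf
      kosambi(min(r, 0.45))
    }, numeric(1))))
    names(pos) <- skel

    classes[skel, "class"] <- "skeleton"
    classes[skel, "group"] <- gname
    for (r in skel) {
      mates <- setdiff(bn$bins[[r]], r)
      classes[mates, "class"] <- "redundant"
      classes[mates, "group"] <- gname
    }

    # attach removed representatives (and their bin mates follow)
    attached <- NULL
    rf_block <- est$rf[, skel, drop = FALSE]
    for (r in osk$removed) {
      iv <- attach_interval(rf_block[r, ], skel, max_rf = attach_max_rf)
      if (is.null(iv)) next
      attached <- rbind(attached, data.frame(
        marker = r, left = iv$left, right = iv$right,
        rf_sum = iv$rf_sum, stringsAsFactors = FALSE))
      att_ids <- bn$bins[[r]]
      classes[att_ids, "class"] <- "attached"
      classes[att_ids, "group"] <- gname
    }
    groups[[gi]] <- list(name = gname,
                         skeleton = data.frame(marker = skel,
                                               position_cM = unname(pos),
                                               stringsAsFactors = FALSE),
                         bins = bn$bins, attached = attached)
  }

  # dual-retained markers: resolve phase against the skeleton, then attach
  for (d in dual) {
    best <- NULL
    for (gi in seq_along(groups)) {
      skel <- groups[[gi]]$skeleton$marker
      near <- skel[seq_len(min(5L, length(skel)))]
      # quick scan: rf of candidate 1 against a few skeleton markers of the
      # group, keeping the group with the tightest linkage under either phase
      rfs <- vapply(near, function(s) {
        r1 <- tryCatch(estimate_rf(phased$geno[, d], geno[, s],
                                   scores[d], scores[s])$rf, error = function(e) NA)
        if (is.na(r1)) return(NA_real_)
        min(r1, 1 - r1)  # phase-swapped candidate mirrors the estimate
      }, numeric(1))
      if (all(is.na(rfs))) next
      sc <- min(rfs, na.rm = TRUE)
      if (is.null(best) || sc < best$sc) best <- list(gi = gi, sc = sc)
    }
    if (is.null(best) || best$sc > attach_max_rf) next
    gi <- best$gi
    skel <- groups[[gi]]$skeleton$marker
    res <- tryCatch(
      resolve_dual_phase(phased$geno[, d], scores[d],
                         geno[, skel[seq_len(min(3L, length(skel)))], drop = FALSE],
                         scores[skel[seq_len(min(3L, length(skel)))]]),
      error = function(e) NULL)
    if (is.null(res)) next
    rfv <- vapply(skel, function(s)
      tryCatch(estimate_rf(res$phased, geno[, s], res$score, scores[s])$rf,
               error = function(e) 0.5), numeric(1))
    iv <- attach_interval(rfv, skel, max_rf = attach_max_rf)
    if (is.null(iv)) next
    groups[[gi]]$attached <- rbind(groups[[gi]]$attached, data.frame(
      marker = d, left = iv$left, right = iv$right, rf_sum = iv$rf_sum,
      stringsAsFactors = FALSE))
    classes[d, "class"] <- "attached"
    classes[d, "group"] <- groups[[gi]]$name
  }

  # order groups by skeleton length, longest first, and rename
  lens <- vapply(groups, function(g) max(g$skeleton$position_cM), numeric(1))
  groups <- groups[order(-lens)]
  for (gi in seq_along(groups)) {
    old <- groups[[gi]]$name
    groups[[gi]]$name <- sprintf("LG%02d", gi)
    classes$group[!is.na(classes$group) & classes$group == old] <-
      sprintf("LG%02d*", gi)
  }
  classes$group <- sub("\\*$", "", classes$group)
  structure(list(groups = groups, classes = classes,
                 unplaced = classes$marker[classes$class == "unplaced"]),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d linkage groups, %d markers placed, %d unplaced\n",
              length(x$groups), sum(x$classes$class != "unplaced"),
              length(x$unplaced)))
  invisible(x)
}

#' Summary table of a linkage map
#'
#' Per-group skeleton/redundant/attached/total counts, map length (position
#' of the last skeleton marker, 1 decimal), mean adjacent-skeleton interval
#' (`length / (skeleton - 1)`, 2 decimals) and maximum adjacent interval,
#' plus a totals row whose overall mean interval is
#' `total length / (total skeleton - n groups)`.
#'
#' @param map a `genetic_map`.
#' @return data frame in the layout of a published map-summary table.
#' @export
summarize_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- do.call(rbind, lapply(map$groups, function(g) {
    pos <- g$skeleton$position_cM
    nsk <- nrow(g$skeleton)
    nred <- sum(map$classes$group == g$name & map$classes$class == "redundant",
                na.rm = TRUE)
    natt <- sum(map$classes$group == g$name & map$classes$class == "attached",
                na.rm = TRUE)
    data.frame(group = g$name, skeleton = nsk, redundant = nred,
               attached = natt,
               length_cM = round(max(pos), 1),
               max_interval_cM = if (nsk >= 2) round(max(diff(pos)), 1) else NA,
               stringsAsFactors = FALSE)
  }))
  map_summary_table(rows)
}

#' @rdname summarize_map
#' @param rows data frame with columns `group`, `skeleton`, `redundant`,
#'   `attached`, `length_cM` and optionally `max_interval_cM` (one row per
#'   linkage group), from which totals and mean intervals are computed.
#' @export
map_summary_table <- function(rows) {
  need <- c("group", "skeleton", "redundant", "attached", "length_cM")
  if (!all(need %in% names(rows)))
    stop_bad("rows must contain columns: %s", paste(need, collapse = ", "))
  rows$total <- rows$skeleton + rows$redundant + rows$attached
  rows$mean_interval_cM <- ifelse(rows$skeleton >= 2,
                                  round(rows$length_cM / (rows$skeleton - 1), 2),
                                  NA)
  if (!"max_interval_cM" %in% names(rows)) rows$max_interval_cM <- NA
  tot_skel <- sum(rows$skeleton)
  tot_len <- round(sum(rows$length_cM), 1)
  totals <- data.frame(
    group = "Total", skeleton = tot_skel, redundant = sum(rows$redundant),
    attached = sum(rows$attached), length_cM = tot_len,
    max_interval_cM = if (all(is.na(rows$max_interval_cM))) NA
                      else max(rows$max_interval_cM, na.rm = TRUE),
    total = sum(rows$total),
    mean_interval_cM = round(tot_len / (tot_skel - nrow(rows)), 2),
    stringsAsFactors = FALSE)
  out <- rbind(rows[c("group", "skeleton", "redundant", "attached", "total",
                      "length_cM", "mean_interval_cM", "max_interval_cM")],
               totals[c("group", "skeleton", "redundant", "attached", "total",
                        "length_cM", "mean_interval_cM", "max_interval_cM")])
  rownames(out) <- NULL
  out
}

#' Write map tables to TSV
#'
#' Writes the marker table (`group`, `position_cM`, `marker`, `class`) and
#' the summary table.
#'
#' @param map a `genetic_map`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_map <- function(map, prefix) {
  marker_rows <- do.call(rbind, lapply(map$groups, function(g) {
    sk <- data.frame(group = g$name, position_cM = round(g$skeleton$position_cM, 2),
                     marker = g$skeleton$marker, class = "skeleton",
                     stringsAsFactors = FALSE)
    red <- NULL
    for (r in g$skeleton$marker) {
      mates <- setdiff(g$bins[[r]] %||% r, r)
      if (length(mates))
        red <- rbind(red, data.frame(
          group = g$name,
          position_cM = round(g$skeleton$position_cM[g$skeleton$marker == r], 2),
          marker = mates, class = "redundant", stringsAsFactors = FALSE))
    }
    att <- if (!is.null(g$attached))
      data.frame(group = g$name, position_cM = NA, marker = g$attached$marker,
                 class = "attached", stringsAsFactors = FALSE)
    rbind(sk, red, att)
  }))
  f1 <- paste0(prefix, "_markers.tsv")
  f2 <- paste0(prefix, "_summary.tsv")
  utils::write.table(marker_rows, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summarize_map(map), f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f1, f2))
}
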