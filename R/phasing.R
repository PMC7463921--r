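# Phasing of raw F2 genotype calls against the parental controls.
#
# Phased F2 scores are stored as integer class codes per marker:
#   codominant ("co"):       0 = parent-1 homozygote, 1 = het, 2 = parent-2
#   dominant, presence on the parent-1 allele ("dom1"): present -> 0, absent -> 2
#   dominant, presence on the parent-2 allele ("dom2"): present -> 2, absent -> 0
# so that for every score type the code is the genotype class certain from
# the call, and swapping a phase is the involution code -> 2 - code.

phase_codes_snp <- function(f2_calls, a_is_parent1) {
  map <- if (a_is_parent1) c(AA = 0L, AB = 1L, BB = 2L)
         else               c(AA = 2L, AB = 1L, BB = 0L)
  out <- unname(map[f2_calls])
  out[f2_calls == "NN"] <- NA_integer_
  out
}

phase_codes_pav <- function(f2_calls, presence_parent) {
  pres <- if (presence_parent == 1L) 0L else 2L
  out <- ifelse(f2_calls == "P", pres, 2L - pres)
  out[f2_calls == "NN"] <- NA_integer_
  as.integer(out)
}

#' Phase one SNP marker against the parents
#'
#' When at least one parent is homozygous, that parent's allele fixes the
#' parent-1/parent-2 orientation of the F2 calls. When both parents are
#' heterozygous (or missing), both candidate phasings — exact allele swaps of
#' each other — are retained for resolution after linkage mapping.
#'
#' @param parent_calls length-2 character vector, calls of parent 1 and 2.
#' @param f2_calls character vector of F2 calls (`AA`/`AB`/`BB`/`NN`).
#' @return list with `status` (`"resolved"`, `"dual"`, `"excluded"`),
#'   `reason` (for exclusions), `score` (`"co"`), and `phased` — the integer
#'   class codes (candidate 1 when dual; candidate 2 is `2 - phased`).
#' @export
phase_snp <- function(parent_calls, f2_calls) {
  p1 <- parent_calls[1]; p2 <- parent_calls[2]
  seg_classes <- unique(f2_calls[f2_calls != "NN"])
  if (length(seg_classes) <= 1L)
    return(list(status = "excluded", reason = "monomorphic", score = "co",
                phased = NULL))
  hom <- c(p1, p2) %in% c("AA", "BB")
  if (all(hom) && p1 == p2)
    return(list(status = "excluded", reason = "inconsistent_parents",
                score = "co", phased = NULL))
  if (hom[1])
    return(list(status = "resolved", score = "co",
                phased = phase_codes_snp(f2_calls, a_is_parent1 = (p1 == "AA"))))
  if (hom[2])
    return(list(status = "resolved", score = "co",
                phased = phase_codes_snp(f2_calls, a_is_parent1 = (p2 == "BB"))))
  # both heterozygous or missing: dual-retained
  list(status = "dual", score = "co",
       phased = phase_codes_snp(f2_calls, a_is_parent1 = TRUE))
}

#' Phase one PAV (dominant) marker against the parents
#'
#' A heterozygous parent scores `P`, so when both parents are present the
#' coupling parent cannot be read off and both phases are retained. When one
#' parent is absent, presence must come from the other parent, which fixes
#' the orientation even if that parent's own call is missing.
#'
#' @param parent_calls length-2 character vector (`P`/`A`/`NN`).
#' @param f2_calls character vector of F2 calls.
#' @return as [phase_snp()]; `score` is `"dom1"` or `"dom2"` (which parent
#'   carries the presence allele), `"dom1"` for candidate 1 of a dual.
#' @export
phase_pav <- function(parent_calls, f2_calls) {
  p1 <- parent_calls[1]; p2 <- parent_calls[2]
  seg_classes <- unique(f2_calls[f2_calls != "NN"])
  if (length(seg_classes) <= 1L)
    return(list(status = "excluded", reason = "monomorphic", score = NA,
                phased = NULL))
  if (p1 == "A" && p2 == "A")
    return(list(status = "excluded", reason = "inconsistent_parents",
                score = NA, phased = NULL))
  if (p2 == "A")   # presence can only descend from parent 1
    return(list(status = "resolved", score = "dom1",
                phased = phase_codes_pav(f2_calls, 1L)))
  if (p1 == "A")
    return(list(status = "resolved", score = "dom2",
                phased = phase_codes_pav(f2_calls, 2L)))
  # both present (or unreadable): dual-retained, candidate 1 = dom1
  list(status = "dual", score = "dom1",
       phased = phase_codes_pav(f2_calls, 1L))
}

#' Phase a full genotype matrix
#'
#' Applies [phase_snp()] / [phase_pav()] marker by marker and assembles the
#' phased F2 matrix. Missing calls stay missing.
#'
#' @param gm a [genotype_matrix()].
#' @return object of class `phased_genotypes`: list with
#'   `geno` (integer matrix, F2 individuals x retained markers, `NA` =
#'   missing), `markers` (data frame: `id`, `type`, `score`, `phase_state`,
#'   `missing_fraction`), `individuals` (F2 metadata), and `excluded`
#'   (data frame of excluded markers with reasons).
#' @export
phase_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  i1 <- which(gm$individuals$role == "parent1")
  i2 <- which(gm$individuals$role == "parent2")
  f2 <- which(gm$individuals$role == "F2")
  res <- lapply(seq_len(ncol(gm$calls)), function(j) {
    pc <- c(gm$calls[i1, j], gm$calls[i2, j])
    fc <- gm$calls[f2, j]
    if (gm$markers$type[j] == "SNP") phase_snp(pc, fc) else phase_pav(pc, fc)
  })
  keep <- vapply(res, function(r) r$status != "excluded", logical(1))
  geno <- do.call(cbind, lapply(res[keep], `[[`, "phased"))
  if (is.null(geno)) geno <- matrix(NA_integer_, length(f2), 0)
  colnames(geno) <- gm$markers$id[keep]
  rownames(geno) <- gm$individuals$id[f2]
  markers <- data.frame(
    id = gm$markers$id[keep],
    type = gm$markers$type[keep],
    score = vapply(res[keep], function(r) as.character(r$score), character(1)),
    phase_state = vapply(res[keep], function(r)
      if (r$status == "dual") "dual-retained" else "resolved", character(1)),
    missing_fraction = colMeans(is.na(geno)),
    stringsAsFactors = FALSE)
  excluded <- data.frame(
    id = gm$markers$id[!keep],
    reason = vapply(res[!keep], function(r) r$reason, character(1)),
    stringsAsFactors = FALSE)
  structure(list(geno = geno, markers = markers,
                 individuals = gm$individuals[f2, , drop = FALSE],
                 excluded = excluded),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf("phased_genotypes: %d F2 x %d markers (%d dual-retained, %d excluded)\n",
              nrow(x$geno), ncol(x$geno),
              sum(x$markers$phase_state == "dual-retained"), nrow(x$excluded)))
  invisible(x)
}

#' Resolve a dual-retained phase against phased neighbours
#'
#' Picks the candidate phasing that minimises the summed estimated
#' recombination fraction against the nearest unambiguously phased markers of
#' the same linkage group; the allele-swapped candidate gives rf near
#' 0.5 or above, so the choice is sharp. Ties go to the first neighbour's
#' phase with a warning.
#'
#' @param cand integer class codes of candidate 1 (candidate 2 is `2 - cand`).
#' @param score score type of candidate 1 (`"co"`, `"dom1"`, `"dom2"`).
#' @param neighbor_geno integer matrix (individuals x neighbours) of phased
#'   neighbour codes.
#' @param neighbor_scores score types of the neighbours.
#' @return list with `choice` (1 or 2), `phased`, `score`, and `rf` — the
#'   mean rf of each candidate against the neighbours.
#' @export
resolve_dual_phase <- function(cand, score, neighbor_geno, neighbor_scores) {
  if (is.null(neighbor_geno) || ncol(neighbor_geno) == 0L)
    stop_bad("no phased neighbours available; marker stays dual-retained")
  flip_score <- c(co = "co", dom1 = "dom2", dom2 = "dom1")
  mean_rf <- function(g, sc) {
    mean(vapply(seq_len(ncol(neighbor_geno)), function(k) {
      estimate_rf(g, neighbor_geno[, k], sc, neighbor_scores[k])$rf
    }, numeric(1)))
  }
  rf1 <- mean_rf(cand, score)
  rf2 <- mean_rf(2L - cand, flip_score[[score]])
  if (isTRUE(all.equal(rf1, rf2))) {
    warning("candidate phases tie; keeping the orientation of the first neighbour")
    choice <- 1L
  } else choice <- if (rf1 <= rf2) 1L else 2L
  list(choice = choice,
       phased = if (choice == 1L) cand else 2L - cand,
       score = if (choice == 1L) score else flip_score[[score]],
       rf = c(rf1, rf2))
}

#' Flag individuals with excess double crossovers
#'
#' Along a provisional marker order, a genotype run of length one flanked by
#' identical genotypes implies a double crossover in adjacent intervals —
#' overwhelmingly a genotyping error at realistic map densities. Individuals
#' whose count exceeds `median + k * MAD` across the population are flagged.
#'
#' @param phased a `phased_genotypes` object.
#' @param orders list of marker-id vectors, one provisional order per linkage
#'   group.
#' @param k flag threshold in MAD units (default 5).
#' @return data frame with `id`, `double_crossovers`, `flagged`.
#' @export
flag_problem_individuals <- function(phased, orders, k = 5) {
  stopifnot(inherits(phased, "phased_genotypes"))
  if (nrow(phased$geno) < 5L)
    stop_bad("fewer than 5 individuals: no baseline to flag against")
  count_singletons <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3L) return(0L)
    r <- rle(v)
    if (length(r$lengths) < 3L) return(0L)
    inner <- 2:(length(r$lengths) - 1L)
    sum(r$lengths[inner] == 1L &
          r$values[inner - 1L] == r$values[inner + 1L])
  }
  dxo <- rep(0L, nrow(phased$geno))
  for (ord in orders) {
    cols <- match(ord, colnames(phased$geno))
    cols <- cols[!is.na(cols)]
    if (length(cols) < 3L) next
    sub <- phased$geno[, cols, drop = FALSE]
    dxo <- dxo + apply(sub, 1, count_singletons)
  }
  med <- stats::median(dxo)
  mad <- stats::mad(dxo, constant = 1)
  thr <- med + k * max(mad, 0.5)   # floor keeps an all-zero baseline sane
  data.frame(id = rownames(phased$geno), double_crossovers = dxo,
             flagged = dxo > thr, stringsAsFactors = FALSE)
}

#' Filter PAV markers by missingness and drop low-quality batches
#'
#' Sets all PAV calls of the listed sequencing batches to missing (the
#' published analysis discarded every PAV score of its low-coverage Pool1),
#' then removes PAV markers whose missing fraction among F2 individuals
#' exceeds `max_missing`. SNP markers are untouched.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction for a PAV marker.
#' @param drop_batches character vector of batch labels whose PAV calls are
#'   discarded (must exist in the data).
#' @return a filtered [genotype_matrix()].
#' @export
filter_pav_by_missingness <- function(gm, max_missing = 0.2,
                                      drop_batches = character()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  known <- unique(gm$individuals$batch[!is.na(gm$individuals$batch)])
  bad <- setdiff(drop_batches, known)
  if (length(bad) > 0)
    stop_bad("unknown batch label(s): %s", paste(bad, collapse = ", "))
  calls <- gm$calls
  pav <- gm$markers$type == "PAV"
  if (length(drop_batches) > 0) {
    rows <- !is.na(gm$individuals$batch) & gm$individuals$batch %in% drop_batches
    calls[rows, pav] <- "NN"
  }
  f2 <- gm$individuals$role == "F2"
  miss <- colMeans(calls[f2, , drop = FALSE] == "NN")
  keep <- !pav | miss <= max_missing
  genotype_matrix(calls[, keep, drop = FALSE], gm$individuals,
                  gm$markers[keep, , drop = FALSE])
}
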