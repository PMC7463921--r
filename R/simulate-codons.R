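#' Simulate an in-frame codon pair with known substitution counts
#'
#' Builds a random stop-free coding sequence and derives a partner differing
#' from it by exactly `n_syn_changes` synonymous and `n_nonsyn_changes`
#' nonsynonymous single-nucleotide substitutions, each placed in a distinct
#' codon so that the per-codon substitution pathway is unambiguous. Used as a
#' controlled fixture for synonymous-substitution estimators.
#'
#' @param n_codons number of codons.
#' @param n_syn_changes number of synonymous single-site changes.
#' @param n_nonsyn_changes number of nonsynonymous single-site changes.
#' @param seed integer seed.
#' @return list with `seq_a`, `seq_b` (character strings), and `changes`, a
#'   data frame recording codon index, position, base change and class of
#'   every substitution.
#' @examples
#' simulate_codon_pair(10, 2, 1, seed = 42)$changes
#' @export
simulate_codon_pair <- function(n_codons, n_syn_changes, n_nonsyn_changes,
                                seed = 1L) {
  stopifnot(n_codons >= 1, n_syn_changes >= 0, n_nonsyn_changes >= 0)
  if (n_syn_changes + n_nonsyn_changes > n_codons)
    stop_bad("infeasible: %d changes requested on %d codons (one change per codon)",
             n_syn_changes + n_nonsyn_changes, n_codons)

  sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  # codons offering at least one synonymous single-site alternative
  syn_opts <- function(codon) {
    out <- NULL
    for (pos in 1:3) {
      nb <- codon_neighbours(codon, pos)
      keep <- !is_stop(nb) & translate_codon(nb) == translate_codon(codon)
      if (any(keep))
        out <- rbind(out, data.frame(pos = pos, alt = nb[keep],
                                     stringsAsFactors = FALSE))
    }
    out
  }
  nonsyn_opts <- function(codon) {
    out <- NULL
    for (pos in 1:3) {
      nb <- codon_neighbours(codon, pos)
      keep <- !is_stop(nb) & translate_codon(nb) != translate_codon(codon)
      if (any(keep))
        out <- rbind(out, data.frame(pos = pos, alt = nb[keep],
                                     stringsAsFactors = FALSE))
    }
    out
  }
  syn_capable <- sense[vapply(sense, function(cd) !is.null(syn_opts(cd)), logical(1))]

  with_seed(derive_seed(seed, "codon_pair"), {
    codons <- sample(sense, n_codons, replace = TRUE)
    target <- sample(n_codons, n_syn_changes + n_nonsyn_changes)
    syn_idx <- target[seq_len(n_syn_changes)]
    non_idx <- setdiff(target, syn_idx)
    # ensure codons designated for synonymous change can host one
    for (i in syn_idx)
      if (!codons[i] %in% syn_capable) codons[i] <- sample(syn_capable, 1)

    partner <- codons
    changes <- NULL
    for (i in syn_idx) {
      opt <- syn_opts(codons[i])
      pick <- opt[sample(nrow(opt), 1), ]
      partner[i] <- pick$alt
      changes <- rbind(changes, data.frame(
        codon = i, pos = pick$pos,
        from = substr(codons[i], pick$pos, pick$pos),
        to = substr(pick$alt, pick$pos, pick$pos),
        class = "synonymous", stringsAsFactors = FALSE))
    }
    for (i in non_idx) {
      opt <- nonsyn_opts(codons[i])
      pick <- opt[sample(nrow(opt), 1), ]
      partner[i] <- pick$alt
      changes <- rbind(changes, data.frame(
        codon = i, pos = pick$pos,
        from = substr(codons[i], pick$pos, pick$pos),
        to = substr(pick$alt, pick$pos, pick$pos),
        class = "nonsynonymous", stringsAsFactors = FALSE))
    }
    list(seq_a = paste(codons, collapse = ""),
         seq_b = paste(partner, collapse = ""),
         changes = changes %||% data.frame(codon = integer(), pos = integer(),
                                           from = character(), to = character(),
                                           class = character()))
  })
}
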