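#' Configuration for the Ks sample simulator
#'
#' Describes a dated species tree plus whole-genome duplications (WGDs), a
#' clock converting node age to the expected pairwise Ks mode, and the
#' per-gene-pair dispersion around that mode.
#'
#' @param tree rooted tree, as a newick string or `ape::phylo`.
#' @param node_ages numeric vector of internal-node ages in MYA, in
#'   `ape` node-number order (node `Ntip+1` first).
#' @param wgds list of WGD events, each `list(name=, species=, age=)`;
#'   `species` is the set of tip labels descending from the duplication.
#' @param ks_per_mya expected pairwise Ks accumulated per MY of divergence
#'   (both lineages combined).
#' @param dispersion log-scale spread (sdlog) of per-gene-pair Ks around the
#'   mode.
#' @param n_pairs_per_species_pair gene pairs drawn per species pair.
#' @param seed integer seed.
#' @return a `sim_ks_config` list.
#' @export
sim_ks_config <- function(tree, node_ages, wgds = list(),
                          ks_per_mya = 0.0117, dispersion = 0.25,
                          n_pairs_per_species_pair = 5000, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (length(node_ages) != tree$Nnode)
    stop_bad("need %d internal-node ages, got %d", tree$Nnode, length(node_ages))
  if (ks_per_mya <= 0) stop_bad("ks_per_mya must be > 0")
  if (dispersion <= 0) stop_bad("dispersion must be > 0")
  ntip <- length(tree$tip.label)
  # parent age must be >= child age
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    if (c_ > ntip && node_ages[p - ntip] < node_ages[c_ - ntip])
      stop_bad("node ages must decrease from root to leaves")
  }
  structure(list(tree = tree, node_ages = node_ages, wgds = wgds,
                 ks_per_mya = ks_per_mya, dispersion = dispersion,
                 n_pairs = n_pairs_per_species_pair, seed = seed),
            class = "sim_ks_config")
}

#' The default legume-like study system
#'
#' Five species mirroring the psoraleoid/phaseoloid panel with two WGDs:
#' the papilionoid WGD at 56.5 MYA shared by all species and a recent
#' Glycine WGD at 10.4 MYA. Speciation ages: Bituminaria-Glycine 17.4,
#' (Bituminaria,Glycine)-Phaseolus 25.9, Cicer-Trifolium 30.2, crown split
#' 45 MYA.
#'
#' @param ... overrides passed on to [sim_ks_config()].
#' @return a `sim_ks_config`.
#' @export
sim_ks_config_default <- function(...) {
  tree <- "(((Bituminaria,Glycine),Phaseolus),(Cicer,Trifolium));"
  phy <- ape::read.tree(text = tree)
  # internal nodes in ape order: root, ((B,G),P), (B,G), (C,T)
  ages <- c(45, 25.9, 17.4, 30.2)
  wgds <- list(
    list(name = "papilionoid", species = phy$tip.label, age = 56.5),
    list(name = "glycine", species = "Glycine", age = 10.4))
  args <- utils::modifyList(
    list(tree = phy, node_ages = ages, wgds = wgds), list(...))
  do.call(sim_ks_config, args)
}

# age of the MRCA of two tips
mrca_age <- function(cfg, a, b) {
  phy <- cfg$tree
  ntip <- length(phy$tip.label)
  node <- ape::getMRCA(phy, c(a, b))
  cfg$node_ages[node - ntip]
}

# most recent WGD covering a species
recent_wgd_age <- function(cfg, sp) {
  ages <- vapply(cfg$wgds, function(w)
    if (sp %in% w$species) w$age else NA_real_, numeric(1))
  if (all(is.na(ages)))
    stop_bad("no WGD covers species %s: self-pair mode undefined", sp)
  min(ages, na.rm = TRUE)
}

#' Simulate per-species-pair Ks samples
#'
#' For every unordered species pair (including self-pairs) draws
#' `n_pairs_per_species_pair` Ks values from a lognormal whose mode is
#' `ks_per_mya x age`, where age is the MRCA age for cross pairs and the
#' most recent covering WGD for self-pairs.
#'
#' @param cfg a [sim_ks_config()].
#' @return named list of Ks vectors keyed `"A|B"` (names sorted; self-pairs
#'   `"A|A"`); attribute `"modes"` records the ground-truth modes.
#' @export
simulate_ks_samples <- function(cfg) {
  stopifnot(inherits(cfg, "sim_ks_config"))
  sp <- sort(cfg$tree$tip.label)
  with_seed(derive_seed(cfg$seed, "ks"), {
    out <- list(); modes <- numeric(0)
    for (i in seq_along(sp)) for (j in i:length(sp)) {
      a <- sp[i]; b <- sp[j]
      age <- if (a == b) recent_wgd_age(cfg, a) else mrca_age(cfg, a, b)
      m <- cfg$ks_per_mya * age
      key <- paste(a, b, sep = "|")
      sigma <- cfg$dispersion
      out[[key]] <- stats::rlnorm(cfg$n_pairs,
                                  meanlog = log(m) + sigma^2, sdlog = sigma)
      modes[key] <- m
    }
    attr(out, "modes") <- modes
    out
  })
}
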