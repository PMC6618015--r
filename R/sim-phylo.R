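# Phylogeny, Brownian traits and the species-level coupling between
# sexual-dimorphism proxies and balancing-selection intensity.

# Brownian motion along a phylo tree from a root value of 0.
bm_tips <- function(tree, sigma2) {
  if (sigma2 == 0) return(setNames(rep(0, length(tree$tip.label)),
                                   tree$tip.label))
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2))
}

#' Simulate a phylogeny with dimorphism proxies and balancing strengths
#'
#' A random coalescent tree (rescaled to unit depth) carries three
#' Brownian traits standing in for the usual sexual-dimorphism proxies:
#' a dichromatism score (the primary trait, evolving around a positive
#' clade-level baseline `trait_root`, as real dichromatism scores are
#' positive-scale measures), plus sperm number and residual testes mass,
#' each built as 0.5 x dichromatism + an independent Brownian component
#' so that the proxies correlate as such measures do. Species
#' balancing-selection strength is
#' `max(0, coupling * dichromatism + noise)` with Brownian noise of
#' variance `noise_frac * bm_sigma2`, so `coupling = 0` decouples
#' strength from every trait (the null), while `coupling > 0` plants the
#' trait-diversity association the comparative analysis estimates.
#'
#' @param config A [sim_config] (needs `n_species >= 3` for downstream
#'   comparative fits).
#' @return List: `tree` (ape `phylo`), `traits` tibble (`species`,
#'   `dichromatism_score`, `sperm_number`, `residual_testes_mass`),
#'   `balancing_strength` named vector.
#' @export
simulate_phylogeny_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "phylogeny"))
  n <- config$n_species
  tree <- ape::rcoal(n, tip.label = sprintf("sp%d", seq_len(n)))
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth > 0) tree$edge.length <- tree$edge.length / depth
  dich <- config$trait_root + bm_tips(tree, config$bm_sigma2)
  sperm <- 0.5 * dich + bm_tips(tree, config$bm_sigma2)
  testes <- 0.5 * dich + bm_tips(tree, config$bm_sigma2)
  noise <- bm_tips(tree, config$noise_frac * config$bm_sigma2)
  strength <- pmax(config$coupling * dich + noise, 0)
  list(
    tree = tree,
    traits = tibble(species = tree$tip.label,
                    dichromatism_score = unname(dich[tree$tip.label]),
                    sperm_number = unname(sperm[tree$tip.label]),
                    residual_testes_mass = unname(testes[tree$tip.label])),
    balancing_strength = strength[tree$tip.label]
  )
}
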