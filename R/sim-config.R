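# Simulation configuration: the study conditions every synthetic dataset
# is generated under.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with validated
#' defaults representing the study design the pipeline targets: six
#' species, five individuals per sex, gonad + spleen expression, RNA-seq
#' scale read depth, and balancing selection modelled as an
#' intermediate-frequency bump in the site frequency spectrum.
#'
#' @param n_species Number of species (>= 1; comparative stages need >= 3).
#' @param n_individuals_per_sex Diploid individuals per sex (default 5).
#' @param n_genes Genes per species (default 200).
#' @param sites_per_gene Sites per gene (default 50).
#' @param balancing_fraction Fraction of background (non-focal) genes
#'   given the intermediate-frequency-enriched SFS (default 1: ongoing
#'   balancing selection is the rule for genes expressed alike in both
#'   sexes).
#' @param balancing_strength Nonnegative bump strength; 0 is neutral
#'   (default 4).
#' @param mean_depth Mean sequencing depth, reads/site (default 20).
#' @param error_rate Per-base error probability in `[0, 0.5)`
#'   (default 0.01).
#' @param inbreeding_f Per-individual inbreeding coefficient in `[0, 1]`
#'   (default 0).
#' @param nb_dispersion Negative-binomial dispersion of counts
#'   (default 0.2; 0 = Poisson).
#' @param tissue_bias_lfc True tissue-bias effect, log2 units (default 3).
#' @param sex_bias_lfc True sex-bias effect, log2 units (default 2).
#' @param bm_sigma2 Brownian trait rate per unit branch length
#'   (default 1).
#' @param coupling Slope linking species trait to balancing strength
#'   (default 2).
#' @param seed Global integer seed; all stage streams derive from it.
#' @param frac_gonad_biased,frac_spleen_biased Fractions of truly
#'   tissue-biased genes (defaults 0.2 / 0.15).
#' @param frac_sex_biased Fraction of tissue-biased genes that are truly
#'   sex-biased (default 0.25).
#' @param seg_fraction Fraction of sites segregating in the population
#'   (default 0.4).
#' @param pop_two_n Chromosome count of the notional source population
#'   the SFS is drawn over (default 40).
#' @param noise_frac Variance of the Brownian noise on species balancing
#'   strength, as a fraction of `bm_sigma2` (default 0.25).
#' @param frac_z_linked Fraction of genes placed on the Z chromosome
#'   (default 0.1).
#' @param trait_root Clade-level baseline (root value) of the
#'   dichromatism trait (default 1.5), keeping the positive-scale trait
#'   above the zero floor of the coupled balancing strength for most
#'   species.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 6, n_individuals_per_sex = 5,
                       n_genes = 200, sites_per_gene = 50,
                       balancing_fraction = 1, balancing_strength = 4,
                       mean_depth = 20, error_rate = 0.01,
                       inbreeding_f = 0, nb_dispersion = 0.2,
                       tissue_bias_lfc = 3, sex_bias_lfc = 2,
                       bm_sigma2 = 1, coupling = 2, seed = 1,
                       frac_gonad_biased = 0.2, frac_spleen_biased = 0.15,
                       frac_sex_biased = 0.25, seg_fraction = 0.4,
                       pop_two_n = 40, noise_frac = 0.25,
                       frac_z_linked = 0.1, trait_root = 1.5) {
  cfg <- as.list(environment())
  counts <- c("n_species", "n_individuals_per_sex", "n_genes",
              "sites_per_gene", "pop_two_n")
  for (nm in counts) {
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]])) {
      stop_invalid(paste0("`", nm, "` must be a positive integer"))
    }
  }
  props <- c("balancing_fraction", "inbreeding_f", "frac_gonad_biased",
             "frac_spleen_biased", "frac_sex_biased", "seg_fraction",
             "frac_z_linked")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop_invalid(paste0("`", nm, "` must lie in [0, 1]"))
    }
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5) {
    stop_invalid("`error_rate` must lie in [0, 0.5)")
  }
  if (cfg$balancing_strength < 0) {
    stop_invalid("`balancing_strength` must be nonnegative")
  }
  if (cfg$mean_depth < 0) stop_invalid("`mean_depth` must be nonnegative")
  if (cfg$nb_dispersion < 0) stop_invalid("`nb_dispersion` must be >= 0")
  if (cfg$bm_sigma2 < 0) stop_invalid("`bm_sigma2` must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}
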