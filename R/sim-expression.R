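# Synthetic RNA-seq counts with planted tissue- and sex-bias effects.

#' Simulate an expression count matrix with truth labels
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(tissue effect) * 2^(sex effect) * (length / 1e3) *
#' library factor` and dispersion `nb_dispersion` (0 gives Poisson).
#' Designated gene subsets carry the configured tissue-bias and sex-bias
#' log2 fold changes; annotation carries true length, GC fraction and
#' immune flags; truth labels are returned for recovery tests.
#'
#' @param config A [sim_config].
#' @param species Species label stamped into sample ids (default "sp1").
#' @return List with `counts` (tibble, first column `gene`), `samples`
#'   (sample sheet), `annotation`, and `truth` (per-gene true classes and
#'   effects).
#' @export
simulate_counts <- function(config, species = "sp1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, paste0("counts_", species)))
  n_genes <- config$n_genes
  genes <- sprintf("%s_g%03d", species, seq_len(n_genes))

  n_gonad <- round(config$frac_gonad_biased * n_genes)
  n_spleen <- round(config$frac_spleen_biased * n_genes)
  tissue_truth <- rep("non-tissue-biased", n_genes)
  tissue_truth[seq_len(n_gonad)] <- "gonad-biased"
  if (n_spleen > 0) {
    tissue_truth[n_gonad + seq_len(n_spleen)] <- "spleen-biased"
  }
  sex_truth <- rep("unbiased", n_genes)
  biased_idx <- which(tissue_truth != "non-tissue-biased")
  n_sex <- round(config$frac_sex_biased * length(biased_idx))
  if (n_sex > 0) {
    chosen <- biased_idx[seq_len(n_sex)]
    sex_truth[chosen] <- rep(c("male-biased", "female-biased"),
                             length.out = n_sex)
  }

  n_ind <- config$n_individuals_per_sex
  samples <- tidyr::expand_grid(
    sex = c("male", "female"),
    idx = seq_len(n_ind),
    tissue = c("gonad", "spleen")
  ) |>
    mutate(
      individual = sprintf("%s_%s%d", species, substr(.data$sex, 1, 1),
                           .data$idx),
      sample = paste(.data$individual, .data$tissue, sep = "_"),
      species = species
    ) |>
    select("sample", "species", "individual", "sex", "tissue")

  z_linked <- runif(n_genes) < config$frac_z_linked
  length_bp <- pmax(200, round(rlnorm(n_genes, log(1500), 0.4)))
  gc <- pmin(0.8, pmax(0.2, rnorm(n_genes, 0.5, 0.07)))
  immune <- runif(n_genes) < 0.05
  baseline <- rlnorm(n_genes, log(50), 1)
  lib_factor <- rlnorm(nrow(samples), 0, 0.1)

  t_eff <- matrix(0, n_genes, nrow(samples))
  s_eff <- matrix(0, n_genes, nrow(samples))
  gonad_cols <- samples$tissue == "gonad"
  male_cols <- samples$sex == "male"
  t_eff[tissue_truth == "gonad-biased", gonad_cols] <- config$tissue_bias_lfc
  t_eff[tissue_truth == "spleen-biased", !gonad_cols] <- config$tissue_bias_lfc
  s_eff[sex_truth == "male-biased", male_cols] <- config$sex_bias_lfc
  s_eff[sex_truth == "female-biased", !male_cols] <- config$sex_bias_lfc

  mu <- baseline * (length_bp / 1e3) * 2^(t_eff + s_eff)
  mu <- sweep(mu, 2, lib_factor, "*")
  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = as.vector(mu),
                   size = 1 / config$nb_dispersion), n_genes)
  } else {
    matrix(rpois(length(mu), as.vector(mu)), n_genes)
  }
  dimnames(counts) <- list(genes, samples$sample)

  list(
    counts = as_tibble(counts, rownames = "gene"),
    samples = samples,
    annotation = tibble(gene = genes,
                        chrom_class = if_else(z_linked, "Z", "A"),
                        length_bp = length_bp, gc_fraction = gc,
                        immune_flag = immune),
    truth = tibble(gene = genes, tissue_class = tissue_truth,
                   sex_class = sex_truth,
                   tissue_lfc = config$tissue_bias_lfc *
                     (tissue_truth != "non-tissue-biased"),
                   sex_lfc = config$sex_bias_lfc *
                     (sex_truth != "unbiased"))
  )
}
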