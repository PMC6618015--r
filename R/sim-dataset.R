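# Whole-dataset simulation: compose counts, genotypes and genotype
# likelihoods for one species or a multi-species study, and write every
# input file the pipeline consumes.

#' Simulate the complete input bundle for one species
#'
#' Expression counts come from [simulate_counts]; population-genetic data
#' are generated gene by gene from SFS shapes whose balancing strength
#' depends on the gene's true tissue class: truly gonad-biased genes get
#' `focal_strength`, and a `balancing_fraction` subset of the remaining
#' genes gets `background_strength` (the rest are neutral). Sequencing
#' depth is coupled to expression by scaling the per-gene mean depth with
#' a decile multiplier (0.5x for the least expressed decile to 1.5x for
#' the most), emulating the uneven coverage of transcriptome data. Males
#' and females share the same site frequencies, so intersexual
#' differentiation is null by construction.
#'
#' @param config A [sim_config].
#' @param species Species label (default `"sp1"`).
#' @param focal_strength Balancing strength for truly gonad-biased genes
#'   (default 0: conflict resolved in the focal class).
#' @param background_strength Strength for the balanced background subset
#'   (default `config$balancing_strength`).
#' @return List: `gl` ([gl_table]), `gene_map`, `counts`, `samples`,
#'   `annotation`, `truth` (with per-gene `strength` column), `genotypes`
#'   (integer matrix, sites x individuals).
#' @export
simulate_species_dataset <- function(config, species = "sp1",
                                     focal_strength = 0,
                                     background_strength =
                                       config$balancing_strength) {
  stopifnot(inherits(config, "sim_config"))
  bundle <- simulate_counts(config, species)
  genes <- bundle$truth$gene
  n_genes <- length(genes)
  set.seed(derive_seed(config$seed, paste0("popgen_", species)))

  strength <- rep(0, n_genes)
  focal <- bundle$truth$tissue_class == "gonad-biased"
  strength[focal] <- focal_strength
  bg <- which(!focal)
  balanced_bg <- bg[runif(length(bg)) < config$balancing_fraction]
  strength[balanced_bg] <- background_strength

  # expression-decile depth multiplier (RNA-seq depth tracks expression)
  mean_expr <- rowMeans(count_matrix(bundle$counts))
  decile <- dplyr::ntile(mean_expr, 10)
  gene_mult <- seq(0.5, 1.5, length.out = 10)[decile]

  s <- config$sites_per_gene
  freqs <- unlist(lapply(seq_len(n_genes), function(i) {
    shape <- simulate_sfs_shape(config$pop_two_n, strength[i])
    draw_site_freqs(s, shape, config$seg_fraction, config$pop_two_n)
  }))
  sites <- tibble(gene = rep(genes, each = s),
                  pos = rep(seq_len(s), n_genes))
  n_ind <- 2 * config$n_individuals_per_sex
  seg <- !is.na(freqs)
  geno <- matrix(0L, length(freqs), n_ind)
  if (any(seg)) {
    geno[seg, ] <- simulate_genotypes(freqs[seg], n_ind,
                                      f = config$inbreeding_f,
                                      seed = derive_seed(config$seed,
                                                         paste0("geno_",
                                                                species)))
  }
  sex <- rep(c("male", "female"), each = config$n_individuals_per_sex)
  gl <- simulate_genotype_likelihoods(
    geno, config$mean_depth, config$error_rate,
    seed = derive_seed(config$seed, paste0("gl_", species)),
    sites = sites, sex = sex,
    depth_multiplier = rep(gene_mult, each = s)
  )
  gene_map <- tibble(
    gene = genes,
    chrom_class = bundle$annotation$chrom_class,
    start = 1L, end = as.integer(s)
  )
  truth <- bundle$truth
  truth$strength <- strength
  list(gl = gl, gene_map = gene_map, counts = bundle$counts,
       samples = bundle$samples, annotation = bundle$annotation,
       truth = truth, genotypes = geno, site_freqs = freqs)
}

#' Simulate a multi-species comparative study
#'
#' Draws the phylogeny, trait proxies and per-species balancing strengths
#' with [simulate_phylogeny_traits], then one species bundle each, where
#' the species' coupled strength drives its truly gonad-biased genes and
#' the background balancing strength is shared. Genes with the same index
#' are orthologues across species (orthogroup ids `og###`).
#'
#' @param config A [sim_config] with `n_species >= 2` (the
#'   comparative PGLS stage additionally needs >= 3).
#' @return List: `tree`, `traits`, `balancing_strength`, and `species`
#'   (named list of per-species bundles as from
#'   [simulate_species_dataset], each with an `orthogroup` column in its
#'   truth table).
#' @export
simulate_multispecies_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_species < 2) stop_invalid("need at least 2 species")
  phylo <- simulate_phylogeny_traits(config)
  species <- phylo$tree$tip.label
  bundles <- lapply(species, function(sp) {
    b <- simulate_species_dataset(
      config, species = sp,
      focal_strength = unname(phylo$balancing_strength[sp])
    )
    b$truth$orthogroup <- sprintf("og%03d", seq_len(nrow(b$truth)))
    b
  })
  names(bundles) <- species
  list(tree = phylo$tree, traits = phylo$traits,
       balancing_strength = phylo$balancing_strength, species = bundles)
}

#' Write every pipeline input file for a simulated study
#'
#' Materializes a simulated multi-species study as the plain-text formats
#' the pipeline reads: per species a BEAGLE genotype-likelihood file, a
#' gene map TSV, a counts TSV, a sample sheet TSV, an annotation TSV and
#' a truth-label TSV; plus a Newick tree and a species trait TSV.
#'
#' @param config A [sim_config].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list of written paths suitable for
#'   [pipeline_config].
#' @export
simulate_pipeline_inputs <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_multispecies_dataset(config)
  p <- function(...) file.path(outdir, paste0(...))
  species_paths <- imap(sim$species, function(b, sp) {
    write_beagle(b$gl, p(sp, "_gl.beagle"))
    readr::write_tsv(b$gene_map, p(sp, "_genemap.tsv"))
    readr::write_tsv(b$counts, p(sp, "_counts.tsv"))
    readr::write_tsv(b$samples, p(sp, "_samples.tsv"))
    readr::write_tsv(b$annotation, p(sp, "_annotation.tsv"))
    readr::write_tsv(b$truth, p(sp, "_truth.tsv"))
    list(gl = p(sp, "_gl.beagle"), gene_map = p(sp, "_genemap.tsv"),
         counts = p(sp, "_counts.tsv"), samples = p(sp, "_samples.tsv"),
         annotation = p(sp, "_annotation.tsv"), truth = p(sp, "_truth.tsv"))
  })
  ape::write.tree(sim$tree, p("tree.nwk"))
  readr::write_tsv(sim$traits, p("traits.tsv"))
  invisible(list(species = species_paths, tree = p("tree.nwk"),
                 traits = p("traits.tsv")))
}
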