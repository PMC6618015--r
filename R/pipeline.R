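# End-to-end orchestration: expression -> popgen -> F_ST -> gene-class
# statistics -> comparative PGLS, with provenance and deterministic
# outputs.

#' Build and validate a pipeline configuration
#'
#' @param species Named list; each element a list of paths: `gl`
#'   (BEAGLE), `gene_map`, `counts`, `samples`, `annotation`.
#' @param tree Path to a Newick tree (required when `length(species) >=
#'   3` and `comparative = TRUE`).
#' @param traits Path to a species trait TSV (column `species` plus
#'   trait columns).
#' @param outdir Output directory.
#' @param classification_sex Sex whose expression defines tissue bias
#'   (default `"male"`).
#' @param fpkm_min,tissue_lfc,sex_lfc,top_quantile Thresholds (defaults
#'   2, 2, 1, 0.10).
#' @param n_perm,n_subsample Resampling sizes (defaults 1000, 1000).
#' @param include_z Analyse Z-linked genes (male samples only; default
#'   TRUE).
#' @param exclude_immune Drop immune-flagged genes (default TRUE).
#' @param exclude_sex_biased_for_fst Drop sex-biased genes from the
#'   elevated-F_ST count test (default TRUE).
#' @param comparative Run the cross-species PGLS stage (default TRUE).
#' @param seed Global seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(species, tree = NULL, traits = NULL, outdir,
                            classification_sex = "male", fpkm_min = 2,
                            tissue_lfc = 2, sex_lfc = 1,
                            top_quantile = 0.10, n_perm = 1000,
                            n_subsample = 1000, include_z = TRUE,
                            exclude_immune = TRUE,
                            exclude_sex_biased_for_fst = TRUE,
                            comparative = TRUE, seed = 1) {
  cfg <- as.list(environment())
  if (!is.list(species) || length(species) < 1 || is.null(names(species))) {
    stop_invalid("`species` must be a named list of per-species paths")
  }
  if (!classification_sex %in% c("male", "female")) {
    stop_invalid("`classification_sex` must be 'male' or 'female'")
  }
  for (th in c("fpkm_min", "tissue_lfc", "sex_lfc", "top_quantile")) {
    if (cfg[[th]] <= 0) stop_invalid(paste0("`", th, "` must be positive"))
  }
  need <- c("gl", "gene_map", "counts", "samples", "annotation")
  for (sp in names(species)) {
    missing_keys <- setdiff(need, names(species[[sp]]))
    if (length(missing_keys) > 0) {
      stop_invalid(sprintf("species '%s' lacks input path(s): %s", sp,
                           paste(missing_keys, collapse = ", ")))
    }
    for (k in need) {
      if (!file.exists(species[[sp]][[k]])) {
        stop_invalid(sprintf("species '%s': file not found: %s", sp,
                             species[[sp]][[k]]))
      }
    }
  }
  if (comparative && length(species) >= 3) {
    if (is.null(tree) || !file.exists(tree)) {
      stop_invalid("comparative stage enabled but `tree` is missing")
    }
    if (is.null(traits) || !file.exists(traits)) {
      stop_invalid("comparative stage enabled but `traits` is missing")
    }
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "--", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

derive_orthogroup <- function(gene, species) {
  sub(paste0("^", species, "_"), "", gene)
}

#' Run the full pipeline
#'
#' Executes, per species: expression classification (FPKM filter, TMM,
#' tissue/sex bias, immune exclusion), genotype-likelihood popgen
#' (autosomes with all individuals, Z with males only), intersexual
#' F_ST on the autosomes, and gene-class statistics (relative D,
#' Wilcoxon contrasts, covariate regression, polynomial sex-bias fit,
#' elevated-F_ST count test). Across species it flags top-quantile-D
#' orthologues, runs the permutation enrichment of universally
#' sex-biased and universally unbiased classes, fits PGLS of relative D
#' on every trait column, and runs the Z subsampling test. All outputs
#' are TSVs plus a JSON run manifest; a rerun with the same
#' configuration is byte-identical.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, the output directory. Result TSVs carry `species`,
#'   `stage` and `seed` provenance columns.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outdir, "FAILED"))
  seed <- config$seed
  prov <- function(df, sp, stage) {
    df |> mutate(species = sp, stage = stage, seed = seed,
                 .before = 1)
  }
  report <- character(0)
  say <- function(...) report <<- c(report, sprintf(...))

  per_species <- list()
  for (sp in names(config$species)) {
    paths <- config$species[[sp]]
    inputs <- run_stage(paste0("read_", sp), outdir, {
      samples <- readr::read_tsv(paths$samples, show_col_types = FALSE)
      ind <- samples |> distinct(.data$individual, .data$sex)
      list(
        counts = readr::read_tsv(paths$counts, show_col_types = FALSE),
        samples = samples,
        annotation = readr::read_tsv(paths$annotation,
                                     show_col_types = FALSE),
        gene_map = readr::read_tsv(paths$gene_map, show_col_types = FALSE),
        gl = read_beagle(paths$gl, sex = ind$sex)
      )
    })

    cls <- run_stage(paste0("expression_", sp), outdir, {
      cl <- classify_expression(inputs$counts, inputs$samples,
                                inputs$annotation,
                                sex = config$classification_sex,
                                fpkm_min = config$fpkm_min,
                                tissue_lfc = config$tissue_lfc,
                                sex_lfc = config$sex_lfc)
      if (config$exclude_immune) {
        keep <- exclude_flagged_genes(cl$gene, inputs$annotation,
                                      "immune_flag")
        cl <- cl |> filter(.data$gene %in% keep)
      }
      cl
    })

    pg <- run_stage(paste0("popgen_", sp), outdir, {
      chrom <- setNames(inputs$gene_map$chrom_class, inputs$gene_map$gene)
      auto_sites <- which(chrom[inputs$gl$sites$gene] == "A")
      res <- gene_popgen(gl_subset(inputs$gl, sites = auto_sites),
                         chrom_class = chrom)
      if (config$include_z && any(chrom == "Z")) {
        z_sites <- which(chrom[inputs$gl$sites$gene] == "Z")
        if (length(z_sites) > 0) {
          res_z <- gene_popgen(gl_subset(inputs$gl, sites = z_sites),
                               chrom_class = chrom, males_only = TRUE)
          res <- bind_rows(res, res_z)
        }
      }
      res
    })

    fst <- run_stage(paste0("fst_", sp), outdir, {
      chrom <- setNames(inputs$gene_map$chrom_class, inputs$gene_map$gene)
      auto_sites <- which(chrom[inputs$gl$sites$gene] == "A")
      gene_fst_table(gl_subset(inputs$gl, sites = auto_sites))
    })

    stats_sp <- run_stage(paste0("stats_", sp), outdir, {
      tab <- cls |>
        inner_join(pg, by = "gene") |>
        left_join(inputs$annotation |>
                    select("gene", "length_bp", "gc_fraction"),
                  by = "gene")
      auto <- tab |> filter(!.data$z_linked)
      bg <- auto |> filter(.data$tissue_class == "non-tissue-biased")
      contrasts <- map(c("gonad-biased", "spleen-biased"), function(cl_) {
        cl_d <- auto$tajimas_d[auto$tissue_class == cl_]
        if (sum(!is.na(cl_d)) == 0 || sum(!is.na(bg$tajimas_d)) == 0) {
          return(tibble(class = cl_, relative_d = NA_real_,
                        wilcoxon_p = NA_real_, n_class = sum(!is.na(cl_d))))
        }
        wt <- wilcoxon_contrast(cl_d, bg$tajimas_d)
        tibble(class = cl_,
               relative_d = relative_tajimas_d(cl_d, bg$tajimas_d),
               wilcoxon_p = wt$p_value, n_class = wt$n_class)
      }) |> list_rbind()
      reg <- covariate_regression(auto)
      gonad <- auto |> filter(.data$tissue_class == "gonad-biased")
      poly_fit <- if (nrow(gonad) >= 10) {
        glance(polynomial_sexbias_fit(gonad$tajimas_d, gonad$log2fc_sex))
      } else {
        tibble(r_squared = NA_real_, degree = 2L, n = nrow(gonad))
      }
      fst_tab <- auto |> inner_join(fst, by = "gene")
      if (config$exclude_sex_biased_for_fst) {
        fst_tab <- fst_tab |> filter(.data$sex_class == "unbiased")
      }
      fst_tests <- map(c("gonad-biased", "spleen-biased"), function(cl_) {
        foc <- fst_tab$fst[fst_tab$tissue_class == cl_]
        bgf <- fst_tab$fst[fst_tab$tissue_class == "non-tissue-biased"]
        if (sum(!is.na(foc)) == 0 || sum(!is.na(bgf)) == 0) {
          return(tibble(class = cl_, observed = NA_real_,
                        expected = NA_real_, p_value = NA_real_))
        }
        elevated_fst_count_test(foc, bgf) |>
          mutate(class = cl_, .before = 1) |>
          select("class", "observed", "expected", "p_value")
      }) |> list_rbind()
      list(table = tab, contrasts = contrasts, regression = reg,
           poly = poly_fit, fst_tests = fst_tests)
    })

    readr::write_tsv(prov(cls, sp, "expression"),
                     file.path(outdir, paste0(sp, "_classification.tsv")))
    readr::write_tsv(prov(pg, sp, "popgen"),
                     file.path(outdir, paste0(sp, "_popgen.tsv")))
    readr::write_tsv(prov(fst, sp, "fst"),
                     file.path(outdir, paste0(sp, "_fst.tsv")))
    per_species[[sp]] <- c(stats_sp, list(classification = cls,
                                          popgen = pg, fst = fst))
    say("%s: %d genes classified, %d with D, relative D (gonad) = %s", sp,
        nrow(cls), sum(!is.na(pg$tajimas_d)),
        format(stats_sp$contrasts$relative_d[1], digits = 3))
  }

  stats_out <- imap(per_species, function(res, sp) {
    bind_rows(
      res$contrasts |> mutate(test = "relative_d_wilcoxon"),
      res$fst_tests |> mutate(test = "elevated_fst_count") |>
        rename(relative_d = "expected", wilcoxon_p = "p_value",
               n_class = "observed") |>
        select("class", "relative_d", "wilcoxon_p", "n_class", "test"),
    ) |> mutate(species = sp, stage = "stats", seed = seed, .before = 1)
  }) |> list_rbind()
  readr::write_tsv(stats_out, file.path(outdir, "stats_summary.tsv"))
  regression_out <- imap(per_species, function(res, sp) {
    res$regression |> mutate(species = sp, stage = "stats", seed = seed,
                             .before = 1)
  }) |> list_rbind()
  readr::write_tsv(regression_out, file.path(outdir, "covariate_regression.tsv"))

  # cross-species stages
  sp_names <- names(config$species)
  comparative_rows <- tibble(
    species = character(0), stage = character(0), seed = integer(0),
    tissue = character(0), trait = character(0), estimate = numeric(0),
    p_value = numeric(0), lambda = numeric(0), r_squared = numeric(0)
  )
  enrich_out <- NULL
  if (length(sp_names) >= 2) {
    ortho <- imap(per_species, function(res, sp) {
      res$table |>
        filter(!.data$z_linked) |>
        mutate(orthogroup = derive_orthogroup(.data$gene, sp),
               species = sp) |>
        select("species", "orthogroup", "tajimas_d", "sex_class",
               "tissue_class")
    }) |> list_rbind()
    complete_og <- ortho |>
      filter(!is.na(.data$tajimas_d)) |>
      count(.data$orthogroup) |>
      filter(.data$n == length(sp_names)) |>
      pull("orthogroup")
    ortho <- ortho |> filter(.data$orthogroup %in% complete_og)
    enrich_out <- run_stage("enrichment", outdir, {
      if (length(complete_og) < 20) {
        NULL
      } else {
        flags <- flag_top_quantile(ortho, config$top_quantile)
        universal <- universal_top_genes(flags)
        class_tbl <- ortho |>
          summarise(
            universally_sex_biased = all(.data$sex_class != "unbiased"),
            universally_unbiased = all(.data$sex_class == "unbiased"),
            .by = "orthogroup")
        out <- list()
        for (cl_ in c("universally_sex_biased", "universally_unbiased")) {
          members <- class_tbl$orthogroup[class_tbl[[cl_]]]
          if (length(members) > 0) {
            out[[cl_]] <- permutation_enrichment(
              universal, members, complete_og, n_perm = config$n_perm,
              seed = seed) |>
              mutate(class = cl_, .before = 1)
          }
        }
        list_rbind(out)
      }
    })
    if (!is.null(enrich_out)) {
      readr::write_tsv(enrich_out |>
                         mutate(stage = "enrichment", seed = seed),
                       file.path(outdir, "enrichment.tsv"))
    }
  }

  if (config$comparative && length(sp_names) >= 3) {
    comparative_rows <- run_stage("comparative", outdir, {
      tree <- ape::read.tree(config$tree)
      traits <- readr::read_tsv(config$traits, show_col_types = FALSE)
      reld <- imap(per_species, function(res, sp) {
        res$contrasts |>
          mutate(species = sp) |>
          select("species", "class", "relative_d")
      }) |> list_rbind() |>
        tidyr::pivot_wider(names_from = "class",
                           values_from = "relative_d")
      df <- traits |> inner_join(reld, by = "species")
      trait_cols <- setdiff(names(traits), "species")
      rows <- list()
      for (tissue in c("gonad-biased", "spleen-biased")) {
        if (!tissue %in% names(df) || any(!is.finite(df[[tissue]]))) next
        for (tr in trait_cols) {
          fit <- pgls_fit(df, y = tissue, x = tr, tree = tree,
                          lambda = "ML")
          g <- glance(fit)
          rows[[paste(tissue, tr)]] <- tibble(
            species = "all", stage = "comparative", seed = seed,
            tissue = tissue, trait = tr,
            estimate = fit$coefficients$estimate[2],
            p_value = g$p_value, lambda = g$lambda,
            r_squared = g$r_squared)
        }
      }
      list_rbind(rows)
    })
  }
  readr::write_tsv(comparative_rows, file.path(outdir, "comparative_pgls.tsv"))

  # Z-vs-autosome subsampling (needs Z focal genes in every species)
  zsub <- NULL
  if (length(sp_names) >= 3) {
    zsub <- run_stage("z_subsampling", outdir, {
      auto_tbl <- imap(per_species, function(res, sp) {
        res$table |>
          filter(!.data$z_linked,
                 .data$tissue_class %in% c("gonad-biased",
                                           "non-tissue-biased"),
                 !is.na(.data$tajimas_d)) |>
          transmute(species = sp, tajimas_d = .data$tajimas_d,
                    class = if_else(.data$tissue_class == "gonad-biased",
                                    "focal", "background"))
      }) |> list_rbind()
      z_tbl <- imap(per_species, function(res, sp) {
        res$table |>
          filter(.data$z_linked, .data$tissue_class == "gonad-biased",
                 !is.na(.data$tajimas_d)) |>
          transmute(species = sp, tajimas_d = .data$tajimas_d)
      }) |> list_rbind()
      ok <- all(sp_names %in% z_tbl$species) &&
        file.exists(config$traits %||% "")
      if (!ok) {
        NULL
      } else {
        traits <- readr::read_tsv(config$traits, show_col_types = FALSE)
        tr1 <- setdiff(names(traits), "species")[1]
        z_subsampling_test(auto_tbl, z_tbl,
                           traits |> transmute(.data$species,
                                               trait = .data[[tr1]]),
                           n_rep = config$n_subsample, seed = seed) |>
          mutate(trait = tr1, .before = 1)
      }
    })
    if (!is.null(zsub)) {
      readr::write_tsv(zsub |> mutate(stage = "z_subsampling", seed = seed),
                       file.path(outdir, "z_subsampling.tsv"))
    }
  }

  manifest <- list(
    package = "sexconflictr",
    version = as.character(utils::packageVersion("sexconflictr")),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    species = sp_names,
    thresholds = config[c("fpkm_min", "tissue_lfc", "sex_lfc",
                          "top_quantile", "n_perm", "n_subsample")],
    classification_sex = config$classification_sex
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(c("pipeline report", "===============", report),
             file.path(outdir, "report.txt"))
  invisible(outdir)
}
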