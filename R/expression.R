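# Expression normalization, low-expression filtering and tissue-/sex-bias
# classification.
#
# Count tables are tibbles whose first column is `gene` and whose
# remaining columns are samples; sample sheets are tibbles with columns
# `sample`, `species`, `individual`, `sex` and `tissue`.

count_matrix <- function(counts) {
  counts <- as_tibble(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts[[1]]
  storage.mode(m) <- "double"
  m
}

check_sample_sheet <- function(samples, m) {
  samples <- as_tibble(samples)
  need <- c("sample", "individual", "sex", "tissue")
  if (!all(need %in% names(samples))) {
    stop_invalid(paste("sample sheet must carry columns:",
                       paste(need, collapse = ", ")))
  }
  if (!setequal(samples$sample, colnames(m)) ||
      anyDuplicated(samples$sample)) {
    stop_invalid("sample sheet and count matrix columns must match 1:1")
  }
  if (anyDuplicated(samples[, c("individual", "tissue")])) {
    stop_invalid("(individual, tissue) pairs must be unique")
  }
  samples[match(colnames(m), samples$sample), ]
}

#' FPKM from raw counts
#'
#' `FPKM = count / ((length / 1e3) * (library / 1e6))` -- fragments per
#' kilobase of transcript per million mapped reads.
#'
#' @param counts Count tibble (first column `gene`) or matrix.
#' @param gene_length_bp Named (or gene-ordered) vector of transcript
#'   lengths in bp, all positive.
#' @param library_mapped_reads Optional per-sample library sizes; defaults
#'   to column sums. All must be positive.
#' @return Tibble of FPKM values, same shape as `counts`.
#' @export
fpkm <- function(counts, gene_length_bp, library_mapped_reads = NULL) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  len <- if (!is.null(names(gene_length_bp))) {
    gene_length_bp[rownames(m)]
  } else {
    gene_length_bp
  }
  if (any(is.na(len)) || any(len <= 0)) {
    stop_invalid("gene lengths must be positive and cover all genes")
  }
  lib <- library_mapped_reads %||% colSums(m)
  if (any(lib <= 0)) stop_invalid("library sizes must be positive")
  out <- sweep(m / (len / 1e3), 2, lib / 1e6, "/")
  as_tibble(out, rownames = "gene")
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (reference sample chosen by upper
#' quartile, 30% trim on M and 5% on A, precision-weighted mean of M,
#' factors rescaled to geometric mean 1), computed with edgeR, the
#' standard implementation.
#'
#' @param counts Count tibble or matrix of nonnegative counts, >= 2
#'   samples.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  if (ncol(m) < 2) stop_invalid("TMM needs at least two samples")
  if (any(m < 0)) stop_invalid("counts must be nonnegative")
  if (any(colSums(m) == 0)) stop_invalid("all-zero sample in count matrix")
  setNames(edgeR::calcNormFactors(m, method = "TMM"), colnames(m))
}

#' TMM-normalized counts per million
#'
#' CPM on TMM-corrected effective library sizes; the scale on which fold
#' changes are computed.
#'
#' @inheritParams tmm_factors
#' @return Tibble of CPM values (first column `gene`).
#' @export
cpm_tmm <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  f <- tmm_factors(m)
  eff <- colSums(m) * f
  as_tibble(sweep(m, 2, eff / 1e6, "/"), rownames = "gene")
}

#' Filter lowly expressed genes
#'
#' A gene is removed when, in either tissue, the number of individuals
#' with FPKM below `threshold` is half or more of the individuals assayed
#' in that tissue (`>= ceiling(n/2)`); a value exactly at the threshold
#' counts as expressed.
#'
#' @param fpkm_tbl FPKM tibble (first column `gene`) as from [fpkm].
#' @param samples Sample sheet.
#' @param threshold FPKM threshold (default 2).
#' @return Character vector of retained gene ids.
#' @export
filter_low_expression <- function(fpkm_tbl, samples, threshold = 2) {
  m <- count_matrix(fpkm_tbl)
  samples <- check_sample_sheet(samples, m)
  tissues <- unique(samples$tissue)
  if (length(tissues) < 2) stop_invalid("both tissues must be present")
  low_in <- sapply(tissues, function(tt) {
    idx <- samples$tissue == tt
    rowSums(m[, idx, drop = FALSE] < threshold) >= half_of(sum(idx))
  })
  rownames(m)[!apply(low_in, 1, any)]
}

log2_ratio <- function(num, den, offset) log2((num + offset) / (den + offset))

#' Classify tissue-biased genes within one sex
#'
#' Fold change between tissues is computed on group means of normalized
#' expression within the given sex with a pseudo-expression offset
#' (default 1) to handle zeros: `log2((mean gonad + c) / (mean spleen +
#' c))`. Genes at or above `lfc_threshold` are gonad-biased, at or below
#' `-lfc_threshold` spleen-biased, otherwise non-tissue-biased.
#' Thresholds are inclusive.
#'
#' @param expr Normalized expression tibble (first column `gene`),
#'   typically from [cpm_tmm].
#' @param samples Sample sheet.
#' @param sex Which sex's samples define the classification
#'   (`"male"` or `"female"`).
#' @param lfc_threshold Log2 fold-change threshold (default 2).
#' @param offset Pseudo-expression added to both means (default 1).
#' @return Tibble: `gene`, `tissue_class`, `log2fc_tissue`,
#'   `classification_sex`.
#' @export
classify_tissue_bias <- function(expr, samples, sex = "male",
                                 lfc_threshold = 2, offset = 1) {
  m <- count_matrix(expr)
  samples <- check_sample_sheet(samples, m)
  sel <- samples$sex == sex
  if (!any(sel)) stop_invalid(sprintf("no samples for sex '%s'", sex))
  gonad <- sel & samples$tissue == "gonad"
  spleen <- sel & samples$tissue == "spleen"
  if (!any(gonad) || !any(spleen)) {
    stop_invalid("both tissues must have samples for the chosen sex")
  }
  lfc <- unname(log2_ratio(rowMeans(m[, gonad, drop = FALSE]),
                           rowMeans(m[, spleen, drop = FALSE]), offset))
  tibble(
    gene = rownames(m),
    tissue_class = case_when(
      lfc >= lfc_threshold ~ "gonad-biased",
      lfc <= -lfc_threshold ~ "spleen-biased",
      .default = "non-tissue-biased"
    ),
    log2fc_tissue = lfc,
    classification_sex = sex
  )
}

#' Classify sex-biased genes within one tissue
#'
#' `log2((mean male + c) / (mean female + c))` on normalized expression
#' within the given tissue; at or above `lfc_threshold` male-biased, at or
#' below `-lfc_threshold` female-biased, otherwise unbiased. Sex-limited
#' genes (zero expression in one sex) are retained via the offset.
#'
#' @inheritParams classify_tissue_bias
#' @param tissue Tissue whose samples define the contrast.
#' @param gene_set Optional subset of genes to classify (typically one
#'   tissue-biased set).
#' @param lfc_threshold Log2 fold-change threshold (default 1).
#' @return Tibble: `gene`, `sex_class`, `log2fc_sex`.
#' @export
classify_sex_bias <- function(expr, samples, tissue = "gonad",
                              gene_set = NULL, lfc_threshold = 1,
                              offset = 1) {
  m <- count_matrix(expr)
  samples <- check_sample_sheet(samples, m)
  if (!is.null(gene_set)) m <- m[rownames(m) %in% gene_set, , drop = FALSE]
  male <- samples$tissue == tissue & samples$sex == "male"
  female <- samples$tissue == tissue & samples$sex == "female"
  if (!any(male) || !any(female)) {
    stop_invalid("both sexes must have samples in the chosen tissue")
  }
  lfc <- unname(log2_ratio(rowMeans(m[, male, drop = FALSE]),
                           rowMeans(m[, female, drop = FALSE]), offset))
  tibble(
    gene = rownames(m),
    sex_class = case_when(
      lfc >= lfc_threshold ~ "male-biased",
      lfc <= -lfc_threshold ~ "female-biased",
      .default = "unbiased"
    ),
    log2fc_sex = lfc
  )
}

#' Full expression classification for one species
#'
#' FPKM low-expression filter, TMM/CPM normalization, tissue-bias
#' classification within one sex (Z-linked genes in a separate pass, as
#' their dosage profile differs from the autosomes), then sex-bias
#' classification within each tissue-biased set using that tissue's
#' samples. Non-tissue-biased genes receive a sex-bias call from either
#' tissue (biased in either counts as sex-biased), which is the
#' conservative rule when such genes must be excluded from downstream
#' intersexual contrasts.
#'
#' @param counts Raw count tibble (first column `gene`).
#' @param samples Sample sheet.
#' @param annotation Tibble with columns `gene`, `chrom_class`
#'   (`"A"`/`"Z"`), `length_bp`, `gc_fraction`, `immune_flag`.
#' @param sex Classification sex (default `"male"`, with a female switch).
#' @param fpkm_min FPKM filter threshold (default 2).
#' @param tissue_lfc,sex_lfc Fold-change thresholds (defaults 2 and 1).
#' @param offset Pseudo-expression offset (default 1).
#' @return Tibble with one row per retained gene: `gene`, `tissue_class`,
#'   `sex_class`, `log2fc_tissue`, `log2fc_sex`, `classification_sex`,
#'   `z_linked`, `mean_expr` (mean CPM over all samples).
#' @export
classify_expression <- function(counts, samples, annotation, sex = "male",
                                fpkm_min = 2, tissue_lfc = 2, sex_lfc = 1,
                                offset = 1) {
  m <- count_matrix(counts)
  samples <- check_sample_sheet(samples, m)
  annotation <- as_tibble(annotation)
  if (!all(rownames(m) %in% annotation$gene)) {
    stop_invalid("annotation must cover every gene in the count table")
  }
  len <- setNames(annotation$length_bp, annotation$gene)
  keep <- filter_low_expression(fpkm(m, len), samples, fpkm_min)
  m <- m[rownames(m) %in% keep, , drop = FALSE]
  expr <- cpm_tmm(m)
  zmap <- setNames(annotation$chrom_class == "Z", annotation$gene)
  em <- count_matrix(expr)
  classify_block <- function(genes) {
    sub <- as_tibble(em[genes, , drop = FALSE], rownames = "gene")
    tb <- classify_tissue_bias(sub, samples, sex, tissue_lfc, offset)
    sexcalls <- map(c("gonad", "spleen"), function(tt) {
      classify_sex_bias(sub, samples, tt, lfc_threshold = sex_lfc,
                        offset = offset) |>
        rename(sex_class_tt = "sex_class", log2fc_tt = "log2fc_sex") |>
        mutate(tissue = tt)
    }) |> list_rbind()
    tb |>
      left_join(sexcalls |> tidyr::pivot_wider(
        names_from = "tissue", values_from = c("sex_class_tt", "log2fc_tt")),
        by = "gene") |>
      mutate(
        sex_class = case_when(
          tissue_class == "gonad-biased" ~ .data$sex_class_tt_gonad,
          tissue_class == "spleen-biased" ~ .data$sex_class_tt_spleen,
          .data$sex_class_tt_gonad != "unbiased" ~ .data$sex_class_tt_gonad,
          .data$sex_class_tt_spleen != "unbiased" ~ .data$sex_class_tt_spleen,
          .default = "unbiased"
        ),
        log2fc_sex = if_else(tissue_class == "spleen-biased",
                             .data$log2fc_tt_spleen, .data$log2fc_tt_gonad)
      ) |>
      select("gene", "tissue_class", "sex_class", "log2fc_tissue",
             "log2fc_sex", "classification_sex")
  }
  genes <- rownames(em)
  z <- unname(zmap[genes])
  blocks <- list()
  if (any(!z)) blocks <- c(blocks, list(classify_block(genes[!z])))
  if (any(z)) blocks <- c(blocks, list(classify_block(genes[z])))
  out <- list_rbind(blocks) |>
    mutate(z_linked = unname(zmap[.data$gene]),
           mean_expr = rowMeans(em)[.data$gene]) |>
    arrange(match(.data$gene, genes))
  out
}
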