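# Reciprocal-best-hit orthologue selection from BLAST tabular hit tables,
# and flag-based gene exclusion.

check_hit_table <- function(hits, label) {
  hits <- as_tibble(hits)
  need <- c("query", "subject", "evalue", "bitscore", "pident")
  if (!all(need %in% names(hits))) {
    stop_invalid(paste0("hit table '", label, "' must carry columns: ",
                        paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(hits$evalue) | !is.finite(hits$bitscore) |
                 !is.finite(hits$pident))
  if (length(bad) > 0) {
    stop_invalid(sprintf("hit table '%s': malformed row %d", label, bad[1]))
  }
  hits
}

# Best hit per query after e-value / identity filtering. Ties on bitscore
# break to highest percent identity; a remaining tie discards the query.
best_hits <- function(hits, max_evalue, min_pident) {
  hits |>
    filter(.data$evalue <= max_evalue, .data$pident >= min_pident) |>
    group_by(.data$query) |>
    filter(.data$bitscore == max(.data$bitscore)) |>
    filter(.data$pident == max(.data$pident)) |>
    filter(n() == 1) |>
    ungroup() |>
    select("query", "subject")
}

#' Select reciprocal-best-hit orthologues
#'
#' From two BLAST tabular hit tables (A vs B and B vs A), hits are
#' filtered at an e-value cut-off of 1e-10 and a minimum percent identity
#' of 30, the best hit per query is the one with the highest bitscore
#' (ties broken by highest percent identity; a residual tie discards the
#' query), and a pair is an orthologue when each gene is the other's best
#' hit.
#'
#' @param hits_ab,hits_ba Tibbles with columns `query`, `subject`,
#'   `evalue`, `bitscore`, `pident` (BLAST outfmt-6 naming).
#' @param max_evalue E-value cut-off (default 1e-10).
#' @param min_pident Minimum percent identity (default 30).
#' @return Tibble of orthologue pairs: `gene_a`, `gene_b`.
#' @export
select_reciprocal_best_hits <- function(hits_ab, hits_ba,
                                        max_evalue = 1e-10,
                                        min_pident = 30) {
  ab <- best_hits(check_hit_table(hits_ab, "A->B"), max_evalue, min_pident)
  ba <- best_hits(check_hit_table(hits_ba, "B->A"), max_evalue, min_pident)
  ab |>
    inner_join(ba, by = c(query = "subject", subject = "query")) |>
    select(gene_a = "query", gene_b = "subject") |>
    arrange(.data$gene_a)
}

#' Exclude flagged genes
#'
#' Removes genes whose annotation flag is set -- used to drop loci with
#' immune/MHC annotations, whose heterozygote advantage produces
#' balancing-selection signatures unrelated to sexual conflict.
#'
#' @param gene_set Character vector of gene ids.
#' @param annotation Tibble with columns `gene` and the flag column.
#' @param flag Name of the logical flag column (default `"immune_flag"`).
#' @return Character vector of retained genes. Warns when nothing is left.
#' @export
exclude_flagged_genes <- function(gene_set, annotation, flag = "immune_flag") {
  annotation <- as_tibble(annotation)
  if (!all(gene_set %in% annotation$gene)) {
    stop_invalid("annotation must cover the full gene set")
  }
  flagged <- annotation$gene[annotation[[flag]] %in% TRUE]
  out <- setdiff(gene_set, flagged)
  removed <- length(gene_set) - length(out)
  if (removed > 0) {
    message(removed, " flagged gene(s) removed")
  }
  if (length(out) == 0) warn("all genes were flagged; returning empty set")
  out
}
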