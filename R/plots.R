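# Plot methods for the package's result types.

#' @export
autoplot.sfs_fit <- function(object, ...) {
  df <- tibble(j = seq_along(object$sfs) - 1, prob = object$sfs)
  ggplot(df, aes(x = .data$j, y = .data$prob)) +
    geom_col(fill = "steelblue") +
    labs(x = "derived allele count", y = "probability",
         title = "Estimated unfolded site frequency spectrum") +
    theme_minimal()
}

#' @export
autoplot.sfs_shape <- function(object, ...) {
  df <- tibble(j = seq_along(object), prob = as.numeric(object))
  ggplot(df, aes(x = .data$j, y = .data$prob)) +
    geom_col(fill = "darkorange") +
    labs(x = "derived allele count", y = "probability",
         title = "Simulated SFS shape") +
    theme_minimal()
}

#' Distribution of Tajima's D by tissue-bias class
#'
#' The standard per-species contrast figure: per-gene D split by
#' tissue-bias class, with class medians marked.
#'
#' @param gene_table Tibble with columns `tajimas_d` and `tissue_class`
#'   (and optionally `species` for faceting).
#' @return A ggplot object.
#' @export
plot_d_by_class <- function(gene_table) {
  gene_table <- as_tibble(gene_table) |> filter(!is.na(.data$tajimas_d))
  p <- ggplot(gene_table,
              aes(x = .data$tissue_class, y = .data$tajimas_d,
                  fill = .data$tissue_class)) +
    geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    labs(x = NULL, y = "Tajima's D") +
    theme_minimal()
  if ("species" %in% names(gene_table)) {
    p <- p + facet_wrap(~species)
  }
  p
}
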