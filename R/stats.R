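# Gene-class statistics: relative Tajima's D, Wilcoxon contrasts,
# covariate regression, polynomial sex-bias fits, top-quantile permutation
# enrichment and the Z-vs-autosome subsampling test.

#' Relative Tajima's D
#'
#' Difference between the median D of a gene class and the median D of
#' the non-tissue-biased background. Differencing against the
#' within-species background removes species-level demographic signal so
#' the quantity is comparable across species.
#'
#' @param class_d,background_d Numeric vectors of per-gene D (NA
#'   dropped); both must be non-empty.
#' @return Scalar `median(class) - median(background)`.
#' @export
relative_tajimas_d <- function(class_d, background_d) {
  class_d <- class_d[!is.na(class_d)]
  background_d <- background_d[!is.na(background_d)]
  if (length(class_d) == 0 || length(background_d) == 0) {
    stop_invalid("both gene classes must be non-empty")
  }
  median(class_d) - median(background_d)
}

#' Wilcoxon rank-sum contrast between gene classes
#'
#' Two-sided rank-sum test of a class against the background; exact null
#' distribution when both samples have at most 25 values and no ties,
#' normal approximation with tie correction otherwise (the stats::wilcox.test
#' policy).
#'
#' @param class_d,background_d Numeric vectors (NA dropped).
#' @return One-row tibble: `statistic` (W), `p_value`, `n_class`,
#'   `n_background`.
#' @export
wilcoxon_contrast <- function(class_d, background_d) {
  class_d <- class_d[!is.na(class_d)]
  background_d <- background_d[!is.na(background_d)]
  if (length(class_d) == 0 || length(background_d) == 0) {
    stop_invalid("both gene classes must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(class_d, background_d,
                                     exact = NULL, correct = FALSE))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_class = length(class_d), n_background = length(background_d))
}

# add the smallest positive observed value to zeros before logging
log_offset <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0) stop_invalid("covariate has no positive values")
  log(x + ifelse(x <= 0, min(pos), 0))
}

#' Covariate regression of Tajima's D on tissue bias
#'
#' Ordinary least squares of per-gene D on tissue-bias class (reference
#' level: non-tissue-biased) plus log-transformed nuisance covariates:
#' Watterson's theta, gene length, GC fraction and mean expression
#' level. Zeros in a covariate are offset by its smallest positive
#' observed value before the log.
#'
#' @param gene_table Tibble with columns `tajimas_d`, `tissue_class`,
#'   `theta_w`, `length_bp`, `gc_fraction`, `mean_expr`.
#' @return Tibble of model terms: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, with the fitted `lm` attached as attribute
#'   `"model"`.
#' @export
covariate_regression <- function(gene_table) {
  gene_table <- as_tibble(gene_table) |>
    filter(!is.na(.data$tajimas_d))
  n_terms <- 6
  if (nrow(gene_table) < n_terms + 10) {
    stop_invalid("need at least 10 more rows than model terms")
  }
  if (length(unique(gene_table$tissue_class)) < 2) {
    stop_invalid("rank-deficient design: `tissue_class` is constant")
  }
  df <- gene_table |>
    mutate(
      tissue_class = stats::relevel(factor(.data$tissue_class),
                                    ref = "non-tissue-biased"),
      log_tw = log_offset(.data$theta_w),
      log_len = log_offset(.data$length_bp),
      log_gc = log_offset(.data$gc_fraction),
      log_expr = log_offset(.data$mean_expr)
    )
  fit <- lm(tajimas_d ~ tissue_class + log_tw + log_len + log_gc + log_expr,
            data = df)
  cf <- summary(fit)$coefficients
  if (any(is.na(coef(fit)))) {
    stop_invalid(paste("rank-deficient design; collinear terms:",
                       paste(names(coef(fit))[is.na(coef(fit))],
                             collapse = ", ")))
  }
  out <- tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                std_error = unname(cf[, 2]), statistic = unname(cf[, 3]),
                p_value = unname(cf[, 4]))
  attr(out, "model") <- fit
  out
}

#' Polynomial fit of Tajima's D on sex-bias fold change
#'
#' Least-squares fit of D on raw polynomial terms of the sex-bias log2
#' fold change, avoiding the threshold sensitivity of discrete sex-bias
#' classes.
#'
#' @param d Per-gene Tajima's D.
#' @param log2fc_sex Per-gene sex-bias log2 fold change.
#' @param degree Polynomial degree, 1-3 (default 2).
#' @return Object of class `sexbias_poly`: list with `coefficients`
#'   tibble, `r_squared`, `degree`, `n` and the underlying `fit`.
#' @export
polynomial_sexbias_fit <- function(d, log2fc_sex, degree = 2) {
  if (!degree %in% 1:3) stop_invalid("`degree` must be 1, 2 or 3")
  keep <- !is.na(d) & !is.na(log2fc_sex)
  d <- d[keep]
  x <- log2fc_sex[keep]
  if (length(d) <= degree + 1) {
    stop_invalid("need more observations than polynomial terms")
  }
  fit <- lm(d ~ poly(x, degree, raw = TRUE))
  cf <- summary(fit)$coefficients
  structure(
    list(
      coefficients = tibble(term = c("intercept",
                                     paste0("x^", seq_len(degree))),
                            estimate = unname(cf[, 1]),
                            std_error = unname(cf[, 2]),
                            statistic = unname(cf[, 3]),
                            p_value = unname(cf[, 4])),
      r_squared = summary(fit)$r.squared,
      degree = degree, n = length(d), fit = fit
    ),
    class = "sexbias_poly"
  )
}

#' @export
print.sexbias_poly <- function(x, ...) {
  cat("<sexbias_poly> degree", x$degree, "| n =", x$n,
      "| r^2 =", signif(x$r_squared, 3), "\n")
  invisible(x)
}

#' @export
tidy.sexbias_poly <- function(x, ...) x$coefficients

#' @export
glance.sexbias_poly <- function(x, ...) {
  tibble(r_squared = x$r_squared, degree = x$degree, n = x$n)
}

#' Flag genes in the top quantile of Tajima's D per species
#'
#' Within each species' orthologue set, flags genes whose D reaches the
#' empirical `1 - quantile` quantile (type-7, linear interpolation); ties
#' at the cut-off are flagged inclusively.
#'
#' @param d_table Tibble with columns `species`, `orthogroup`,
#'   `tajimas_d`.
#' @param quantile Upper-tail fraction in (0, 1) (default 0.10).
#' @return The input with a logical `top_flag` column.
#' @export
flag_top_quantile <- function(d_table, quantile = 0.10) {
  if (quantile <= 0 || quantile >= 1) {
    stop_invalid("`quantile` must lie in (0, 1)")
  }
  as_tibble(d_table) |>
    mutate(top_flag = .data$tajimas_d >=
             stats::quantile(.data$tajimas_d, 1 - quantile, na.rm = TRUE,
                             type = 7),
           .by = "species")
}

#' Genes flagged in every species
#'
#' @param flagged Output of [flag_top_quantile].
#' @return Character vector of orthogroups whose flag is set in all
#'   species ("universally elevated" genes).
#' @export
universal_top_genes <- function(flagged) {
  flagged |>
    summarise(universal = all(.data$top_flag), .by = "orthogroup") |>
    filter(.data$universal) |>
    pull("orthogroup")
}

#' Permutation enrichment of a gene class among universally elevated genes
#'
#' Tests whether a gene class (e.g. universally sex-biased orthologues)
#' contains more or fewer universally elevated-D genes than random sets
#' of the same size drawn without replacement from the orthologue set.
#' Reports the two-sided empirical p (distance from the permutation mean,
#' with the +1 correction), the one-sided enrichment/depletion tails, and
#' a chi-squared p against the permutation-mean expectation (df = 1).
#'
#' @param universal Character vector of universally elevated orthogroups.
#' @param class_members Character vector: the gene class (non-empty,
#'   subset of `all_genes`).
#' @param all_genes Character vector: the full orthologue set.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `observed`, `perm_mean`, `empirical_p`,
#'   `empirical_p_upper`, `empirical_p_lower`, `chi2_p`, `n_class`,
#'   `n_universal`, `n_perm`.
#' @export
permutation_enrichment <- function(universal, class_members, all_genes,
                                   n_perm = 1000, seed = 1) {
  if (length(class_members) == 0) stop_invalid("gene class is empty")
  if (n_perm < 100) stop_invalid("`n_perm` must be at least 100")
  if (!all(class_members %in% all_genes)) {
    stop_invalid("class members must belong to the orthologue set")
  }
  set.seed(derive_seed(seed, "permutation"))
  is_universal <- all_genes %in% universal
  m <- length(class_members)
  observed <- sum(class_members %in% universal)
  null <- vapply(seq_len(n_perm), function(i) {
    sum(is_universal[sample.int(length(all_genes), m)])
  }, numeric(1))
  mu <- mean(null)
  emp_two <- (1 + sum(abs(null - mu) >= abs(observed - mu))) / (n_perm + 1)
  emp_up <- (1 + sum(null >= observed)) / (n_perm + 1)
  emp_lo <- (1 + sum(null <= observed)) / (n_perm + 1)
  if (mu > 0 && mu < m) {
    chi2 <- (observed - mu)^2 / mu +
      ((m - observed) - (m - mu))^2 / (m - mu)
    chi2_p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2_p <- NA_real_
  }
  tibble(observed = observed, perm_mean = mu, empirical_p = emp_two,
         empirical_p_upper = emp_up, empirical_p_lower = emp_lo,
         chi2_p = chi2_p, n_class = m,
         n_universal = length(universal), n_perm = n_perm)
}

#' Z-versus-autosome subsampling test
#'
#' Asks whether the weaker trait association seen for Z-linked
#' tissue-biased genes is explained by their smaller number. Per
#' replicate and species, autosomal focal genes are subsampled without
#' replacement to the Z-linked count, relative D is recomputed, and the
#' cross-species Pearson correlation and OLS slope of relative D on the
#' trait are recorded. One-sided p-values are the fraction of replicates
#' whose statistic is at or below the observed Z-based value (ties
#' counted).
#'
#' @param autosomal Tibble with `species`, `tajimas_d`, `class`
#'   (`"focal"` / `"background"`).
#' @param z_genes Tibble with `species`, `tajimas_d`: the Z-linked focal
#'   genes.
#' @param traits Tibble with `species` and `trait`.
#' @param n_rep Number of subsampling replicates (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `observed_r`, `observed_slope`, `p_r`,
#'   `p_slope`, `n_rep`.
#' @export
z_subsampling_test <- function(autosomal, z_genes, traits, n_rep = 1000,
                               seed = 1) {
  autosomal <- as_tibble(autosomal)
  z_genes <- as_tibble(z_genes)
  traits <- as_tibble(traits)
  sp <- sort(unique(autosomal$species))
  if (length(sp) < 3) stop_invalid("need at least 3 species")
  if (!setequal(sp, unique(z_genes$species)) ||
      !all(sp %in% traits$species)) {
    stop_invalid("species sets must match across tables")
  }
  tr <- traits$trait[match(sp, traits$species)]
  if (sd(tr) == 0) stop_invalid("trait is constant across species")
  focal <- map(sp, function(s) {
    autosomal$tajimas_d[autosomal$species == s &
                          autosomal$class == "focal"]
  })
  bg_med <- map_dbl(sp, function(s) {
    median(autosomal$tajimas_d[autosomal$species == s &
                                 autosomal$class == "background"],
           na.rm = TRUE)
  })
  z_count <- map_dbl(sp, function(s) sum(z_genes$species == s))
  if (any(z_count < 1)) stop_invalid("every species needs >= 1 Z gene")
  if (any(z_count > lengths(focal))) {
    stop_invalid("Z gene count exceeds autosomal focal count")
  }
  z_rel <- map_dbl(sp, function(s) {
    median(z_genes$tajimas_d[z_genes$species == s], na.rm = TRUE)
  }) - bg_med
  slope_of <- function(y) unname(coef(lm(y ~ tr))[2])
  observed_r <- cor(z_rel, tr)
  observed_slope <- slope_of(z_rel)
  set.seed(derive_seed(seed, "z_subsampling"))
  reps <- vapply(seq_len(n_rep), function(i) {
    rel <- vapply(seq_along(sp), function(k) {
      median(sample(focal[[k]], z_count[k]))
    }, numeric(1)) - bg_med
    c(cor(rel, tr), slope_of(rel))
  }, numeric(2))
  tibble(observed_r = observed_r, observed_slope = observed_slope,
         p_r = mean(reps[1, ] <= observed_r),
         p_slope = mean(reps[2, ] <= observed_slope),
         n_rep = n_rep)
}
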