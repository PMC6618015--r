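# Intersexual Hudson's F_ST: per-sex ML allele frequencies from genotype
# likelihoods, per-site variance components, per-gene ratio-of-sums F_ST,
# and the elevated-F_ST count test.

# Log-likelihood of allele frequency p per site for one set of individuals
# under a Hardy-Weinberg genotype prior; vectorized over sites. Missing
# triples (flat) contribute a constant and are harmless.
loglik_freq <- function(p, L0, L1, L2) {
  tiny <- .Machine$double.xmin
  rowSums(log((1 - p)^2 * L0 + 2 * p * (1 - p) * L1 + p^2 * L2 + tiny))
}

#' Per-sex maximum-likelihood allele frequencies
#'
#' For every site, the derived-allele frequency in each sex is estimated
#' by 1-D maximization of the genotype-likelihood-based likelihood with a
#' Hardy-Weinberg prior (golden-section search on `[0, 1]`, bracket
#' tolerance `tol`). Sites where a sex has no informative individual, or
#' where all triples are flat, get `NA` for that sex.
#'
#' @param gl A [gl_table] (typically already passed through
#'   [filter_sites] with `per_sex = TRUE`).
#' @param tol Golden-section bracket tolerance (default 1e-6).
#' @return Tibble with one row per site: `gene`, `pos`, `p_male`,
#'   `p_female`, `n_male`, `n_female` (allele counts = 2 x informative
#'   individuals).
#' @export
sex_allele_frequencies <- function(gl, tol = 1e-6) {
  one_sex <- function(idx) {
    L0 <- gl$L0[, idx, drop = FALSE]
    L1 <- gl$L1[, idx, drop = FALSE]
    L2 <- gl$L2[, idx, drop = FALSE]
    miss <- gl$missing[, idx, drop = FALSE]
    L0[miss] <- 1 / 3; L1[miss] <- 1 / 3; L2[miss] <- 1 / 3
    n_inf <- rowSums(!miss)
    informative <- n_inf > 0 &
      rowSums(abs(L0 - 1 / 3) > 1e-9 | abs(L1 - 1 / 3) > 1e-9) > 0
    p <- golden_max(function(p) loglik_freq(p, L0, L1, L2),
                    n = nrow(L0), tol = tol)
    p[!informative] <- NA_real_
    list(p = p, n = 2L * n_inf)
  }
  males <- one_sex(which(gl$sex == "male"))
  females <- one_sex(which(gl$sex == "female"))
  tibble(gene = gl$sites$gene, pos = gl$sites$pos,
         p_male = males$p, p_female = females$p,
         n_male = males$n, n_female = females$n)
}

#' Hudson's per-site F_ST variance components
#'
#' The small-sample-robust estimator: between-population component
#' `N_hat = (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`
#' and total component `D_hat = p1 (1 - p2) + p2 (1 - p1)`, where `n1`,
#' `n2` are allele counts. Components are `NA` when either `n <= 1` or a
#' frequency is missing. Vectorized.
#'
#' @param p1,p2 Allele frequencies in the two groups.
#' @param n1,n2 Allele counts (2 x individuals).
#' @return Tibble with columns `n_hat`, `d_hat`.
#' @export
hudson_site <- function(p1, p2, n1, n2) {
  bad <- is.na(p1) | is.na(p2) | n1 <= 1 | n2 <= 1
  n_hat <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  d_hat <- p1 * (1 - p2) + p2 * (1 - p1)
  n_hat[bad] <- NA_real_
  d_hat[bad] <- NA_real_
  tibble(n_hat = n_hat, d_hat = d_hat)
}

#' Per-gene F_ST as a ratio of sums
#'
#' Combines per-site components as
#' `F_ST = sum(N_hat) / sum(D_hat)` -- the weighted-average ("ratio of
#' sums") estimator, not a mean of per-site ratios. The value may be
#' negative; it is `NA` when the summed total component is zero (e.g. all
#' sites monomorphic).
#'
#' @param n_hat,d_hat Per-site components (NA sites are dropped).
#' @return Scalar F_ST or `NA`.
#' @export
gene_fst <- function(n_hat, d_hat) {
  keep <- !is.na(n_hat) & !is.na(d_hat)
  if (!any(keep)) return(NA_real_)
  sd_ <- sum(d_hat[keep])
  if (sd_ <= 0) return(NA_real_)
  sum(n_hat[keep]) / sd_
}

#' Per-gene intersexual F_ST from a genotype-likelihood table
#'
#' Applies the per-sex data filter, estimates per-sex ML allele
#' frequencies, computes Hudson components and combines them per gene as
#' a ratio of sums. The Z chromosome carries no usable intersexual signal
#' at these sample sizes (females are hemizygous) and should be excluded
#' upstream.
#'
#' @param gl A [gl_table].
#' @param min_ind_fraction Per-sex site filter threshold (default 0.5).
#' @return Tibble: `gene`, `fst`, `n_sites`.
#' @export
gene_fst_table <- function(gl, min_ind_fraction = 0.5) {
  gl <- filter_sites(gl, min_ind_fraction, per_sex = TRUE)
  if (nrow(gl$L0) < 1) stop_invalid("no sites left after per-sex filtering")
  freqs <- sex_allele_frequencies(gl)
  comp <- hudson_site(freqs$p_male, freqs$p_female, freqs$n_male,
                      freqs$n_female)
  tibble(gene = freqs$gene, n_hat = comp$n_hat, d_hat = comp$d_hat) |>
    summarise(fst = gene_fst(.data$n_hat, .data$d_hat), n_sites = n(),
              .by = "gene")
}

#' Count test for elevated intersexual F_ST
#'
#' Compares the number of focal-class genes with `F_ST > 0` against the
#' expectation derived from a background class: `expected = n_focal x
#' fraction(background > 0)`. Significance comes from a 2x2 chi-squared
#' test (class x elevated/not, df = 1, no continuity correction).
#'
#' @param fst_focal,fst_background Numeric vectors of per-gene F_ST
#'   (NA dropped).
#' @return One-row tibble: `observed`, `expected`, `chi2`, `p_value`,
#'   `n_focal`, `n_background`.
#' @export
elevated_fst_count_test <- function(fst_focal, fst_background) {
  fst_focal <- fst_focal[!is.na(fst_focal)]
  fst_background <- fst_background[!is.na(fst_background)]
  if (length(fst_focal) == 0 || length(fst_background) == 0) {
    stop_invalid("both focal and background classes must be non-empty")
  }
  obs <- sum(fst_focal > 0)
  expected <- length(fst_focal) * mean(fst_background > 0)
  tab <- matrix(c(obs, length(fst_focal) - obs,
                  sum(fst_background > 0),
                  sum(fst_background <= 0)), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    chi2 <- 0
    p <- 1
  } else {
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    chi2 <- sum((tab - e)^2 / e)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  tibble(observed = obs, expected = expected, chi2 = chi2, p_value = p,
         n_focal = length(fst_focal), n_background = length(fst_background))
}
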