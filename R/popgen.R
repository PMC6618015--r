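# Genotype-likelihood population genetics: per-read genotype likelihoods,
# sample-allele-frequency (SAF) likelihoods, EM estimation of the unfolded
# SFS, posterior theta estimators and per-gene Tajima's D.

#' Genotype likelihoods from read bases
#'
#' Per-read mixture model for a diploid site: a read matches the derived
#' allele with probability `(g/2) * (1 - eps) + (1 - g/2) * eps/3` under
#' genotype `g` in 0/1/2 derived copies (match probability `1 - eps`,
#' specific mismatch `eps/3`). The three per-genotype products over reads
#' are returned normalized to sum 1; with no reads the flat triple
#' `(1/3, 1/3, 1/3)` is returned.
#'
#' @param bases Logical/0-1 vector, `TRUE` where the read matches the
#'   derived allele.
#' @param error_rates Per-read error probability, in `[0, 0.5)`; recycled.
#' @return Numeric length-3 vector `(L0, L1, L2)` summing to 1.
#' @export
#' @examples
#' genotype_likelihood(c(TRUE), 1e-12)        # one derived read
#' genotype_likelihood(logical(0), 0.01)      # no data -> flat
genotype_likelihood <- function(bases, error_rates) {
  if (any(error_rates < 0 | error_rates >= 0.5)) {
    stop_invalid("error rates must lie in [0, 0.5)")
  }
  if (length(bases) == 0) return(rep(1 / 3, 3))
  bases <- as.logical(bases)
  eps <- rep_len(error_rates, length(bases))
  lik <- vapply(0:2, function(g) {
    p_derived <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
    prod(ifelse(bases, p_derived, 1 - p_derived))
  }, numeric(1))
  normalize_sum1(lik)
}

# Closed-form genotype likelihoods from (derived reads, total reads, eps),
# vectorized over sites x individuals. Returns normalized triples.
gl_from_read_counts <- function(k, d, eps) {
  out <- vector("list", 3)
  for (g in 0:2) {
    pd <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
    out[[g + 1]] <- pd^k * (1 - pd)^(d - k)
  }
  tot <- out[[1]] + out[[2]] + out[[3]]
  flat <- d == 0 | tot == 0
  lapply(out, function(L) {
    L <- L / ifelse(tot == 0, 1, tot)
    L[flat] <- 1 / 3
    L
  })
}

#' Sample allele frequency likelihood at one site
#'
#' Dynamic-programming marginalization of genotype uncertainty: with
#' per-individual genotype likelihoods `g_i(g)` the likelihood of `j`
#' derived alleles among the `2N` sampled chromosomes is
#' `h(j) = w_N(j) / choose(2N, j)` where `w` accumulates
#' `w_i(k) = sum_g w_{i-1}(k - g) * g_i(g) * choose(2, g)`.
#' The vector is scaled to maximum 1. Missing individuals must be excluded
#' by the caller; the vector length adapts to the informative `2N`.
#'
#' @param triples Numeric N x 3 matrix of per-individual genotype
#'   likelihood triples (rows need not be normalized).
#' @return Numeric vector `h(j)`, `j = 0..2N`, max-scaled to 1.
#' @export
saf_likelihood <- function(triples) {
  triples <- matrix(as.numeric(triples), ncol = 3)
  if (nrow(triples) < 1) stop_invalid("site has no informative individuals")
  w <- 1
  for (i in seq_len(nrow(triples))) {
    g <- triples[i, ]
    wn <- numeric(length(w) + 2)
    wn[seq_along(w)]     <- wn[seq_along(w)]     + w * g[1]      # g = 0
    wn[seq_along(w) + 1] <- wn[seq_along(w) + 1] + w * 2 * g[2]  # g = 1
    wn[seq_along(w) + 2] <- wn[seq_along(w) + 2] + w * g[3]      # g = 2
    w <- wn
  }
  two_n <- nrow(triples) * 2
  h <- w / choose(two_n, 0:two_n)
  if (max(h) <= 0) stop_invalid("site carries an all-zero likelihood")
  h / max(h)
}

#' SAF likelihoods for every site of a genotype-likelihood table
#'
#' Vectorized version of [saf_likelihood] over all sites. Missing
#' individual-sites enter as flat triples (the no-data likelihood),
#' keeping a common 2N so that all sites can share one site frequency
#' spectrum.
#'
#' @param gl A [gl_table].
#' @return Sites x (2N + 1) matrix of SAF likelihoods, rows max-scaled
#'   to 1.
#' @export
saf_matrix <- function(gl) {
  L0 <- gl$L0; L1 <- gl$L1; L2 <- gl$L2
  L0[gl$missing] <- 1 / 3
  L1[gl$missing] <- 1 / 3
  L2[gl$missing] <- 1 / 3
  n_sites <- nrow(L0)
  n_ind <- ncol(L0)
  w <- matrix(1, n_sites, 1)
  for (i in seq_len(n_ind)) {
    wn <- matrix(0, n_sites, ncol(w) + 2)
    wn[, seq_len(ncol(w))]     <- wn[, seq_len(ncol(w))] + w * L0[, i]
    wn[, seq_len(ncol(w)) + 1] <- wn[, seq_len(ncol(w)) + 1] + w * 2 * L1[, i]
    wn[, seq_len(ncol(w)) + 2] <- wn[, seq_len(ncol(w)) + 2] + w * L2[, i]
    w <- wn
  }
  two_n <- 2L * n_ind
  h <- sweep(w, 2, choose(two_n, 0:two_n), "/")
  h / pmax(apply(h, 1, max), .Machine$double.xmin)
}

#' Estimate the unfolded site frequency spectrum by EM
#'
#' Maximum-likelihood SFS from per-site sample-allele-frequency
#' likelihoods: E-step `q_s(j) propto xi_j * h_s(j)`, M-step
#' `xi'_j = mean_s q_s(j)`, iterated from a uniform start until the
#' largest coordinate change falls below `tol`. The marginal
#' log-likelihood is non-decreasing at every step and is returned as a
#' trace.
#'
#' @param saf Numeric sites x (2N + 1) matrix of SAF likelihoods.
#' @param tol Convergence tolerance on `max |delta xi|` (default 1e-8).
#' @param max_iter Maximum EM iterations (default 200).
#' @param init Initialization: `"uniform"` (default), or `"sample"`,
#'   which draws one allele frequency per site from its normalized SAF
#'   likelihood and starts from that histogram (a seeded, noisier
#'   variant).
#' @param seed Seed for the `"sample"` initialization.
#' @return An object of class `sfs_fit`: list with `sfs` (probability
#'   vector over 0..2N), `loglik` trace, `iterations`, `converged`.
#'   Non-convergence sets `converged = FALSE` with a warning, not an error.
#' @export
estimate_sfs_em <- function(saf, tol = 1e-8, max_iter = 200,
                            init = c("uniform", "sample"), seed = 1) {
  saf <- as.matrix(saf)
  if (nrow(saf) < 1) stop_invalid("need at least one site")
  k <- ncol(saf)
  init <- match.arg(init)
  if (init == "uniform") {
    xi <- rep(1 / k, k)
  } else {
    set.seed(derive_seed(seed, "sfs_init"))
    draws <- apply(saf, 1, function(h) sample.int(k, 1, prob = h))
    # keep every class reachable: mix with a whiff of uniform
    xi <- normalize_sum1(tabulate(draws, k) + 0.5)
  }
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    m <- sweep(saf, 2, xi, "*")
    denom <- rowSums(m)
    if (any(denom <= 0)) stop_invalid("site with zero marginal likelihood")
    ll <- c(ll, sum(log(denom)))
    xi_new <- colMeans(m / denom)
    delta <- max(abs(xi_new - xi))
    xi <- xi_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("SFS EM did not converge within `max_iter` iterations")
  }
  structure(
    list(sfs = xi, loglik = ll, iterations = iter, converged = converged),
    class = "sfs_fit"
  )
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat("<sfs_fit> 2N =", length(x$sfs) - 1, "|", x$iterations,
      "EM iterations |", if (x$converged) "converged" else "NOT converged",
      "\n")
  invisible(x)
}

#' Per-site posterior allele-frequency probabilities
#'
#' Combines SAF likelihoods with the estimated SFS as prior:
#' `post_s(j) = xi_j h_s(j) / sum_k xi_k h_s(k)`. Sites whose normalizer is
#' zero are returned as `NA` rows (uninformative).
#'
#' @param saf Sites x (2N + 1) SAF matrix.
#' @param sfs Probability vector over 0..2N (or an `sfs_fit`).
#' @return Sites x (2N + 1) matrix of posteriors, rows summing to 1.
#' @export
site_posteriors <- function(saf, sfs) {
  if (inherits(sfs, "sfs_fit")) sfs <- sfs$sfs
  saf <- as.matrix(saf)
  if (length(sfs) != ncol(saf)) stop_invalid("SFS length must match SAF")
  m <- sweep(saf, 2, sfs, "*")
  denom <- rowSums(m)
  out <- m / ifelse(denom > 0, denom, 1)
  out[denom <= 0, ] <- NA_real_
  out
}

#' Posterior-weighted theta estimators for one gene
#'
#' Per site, the probability of being variable is
#' `p_var = 1 - post(0) - post(2N)`; the Watterson contribution is
#' `p_var / a1` with `a1 = sum_{i=1}^{2N-1} 1/i`, and the pairwise
#' contribution is `sum_j post(j) * j * (2N - j) / choose(2N, 2)`. Gene
#' values are sums over sites; the effective number of segregating sites
#' is `S_eff = sum p_var`.
#'
#' @param posteriors Sites x (2N + 1) posterior matrix for the gene's
#'   sites (NA rows are dropped).
#' @return One-row tibble: `theta_w`, `theta_pi`, `s_eff`, `n_sites`.
#' @export
gene_thetas <- function(posteriors) {
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, nrow = 1)
  posteriors <- as.matrix(posteriors)
  keep <- complete.cases(posteriors)
  posteriors <- posteriors[keep, , drop = FALSE]
  if (nrow(posteriors) < 1) stop_invalid("gene has no informative sites")
  two_n <- ncol(posteriors) - 1
  j <- 0:two_n
  a1 <- sum(1 / seq_len(two_n - 1))
  p_var <- 1 - posteriors[, 1] - posteriors[, two_n + 1]
  pi_site <- as.numeric(posteriors %*% (j * (two_n - j))) / choose(two_n, 2)
  tibble(theta_w = sum(p_var) / a1, theta_pi = sum(pi_site),
         s_eff = sum(p_var), n_sites = nrow(posteriors))
}

#' Tajima's D from theta estimates
#'
#' Standard normalization with `n = two_n` sampled chromosomes:
#' `D = (theta_pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))` using the
#' classical constants a1, a2, b1, b2, c1, c2, e1, e2. Returns `NA` when
#' the effective number of segregating sites is not positive.
#'
#' @param theta_w,theta_pi Gene-level theta estimates.
#' @param s_eff Effective number of segregating sites.
#' @param two_n Number of sampled chromosomes (>= 4).
#' @return Tajima's D (scalar, possibly `NA`).
#' @export
tajimas_d <- function(theta_w, theta_pi, s_eff, two_n) {
  if (two_n < 4) stop_invalid("Tajima's D requires two_n >= 4")
  if (is.na(s_eff) || s_eff <= 0) return(NA_real_)
  n <- two_n
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * s_eff + e2 * s_eff * (s_eff - 1)
  if (v <= 0) return(NA_real_)
  (theta_pi - theta_w) / sqrt(v)
}

#' Per-gene population-genetic summaries from genotype likelihoods
#'
#' Full per-gene pipeline: filter sites on data availability, compute SAF
#' likelihoods, estimate one pooled unfolded SFS by EM (the prior), then
#' per-gene posterior thetas and Tajima's D. Z-linked genes should be
#' analysed with male samples only; pass `males_only = TRUE` for that
#' pass.
#'
#' @param gl A [gl_table] whose `sites$gene` assigns sites to genes.
#' @param chrom_class Optional named vector mapping gene -> `"A"`/`"Z"`,
#'   carried through to the output.
#' @param males_only Restrict to male individuals (Z-chromosome mode).
#' @param min_ind_fraction Site filter threshold (default 0.5).
#' @param sfs Optionally, a precomputed `sfs_fit` or probability vector to
#'   use as prior instead of re-estimating.
#' @return Tibble with one row per gene: `gene`, `n_sites`, `s_eff`,
#'   `theta_w`, `theta_pi`, `tajimas_d`, `chrom_class`. The fitted SFS is
#'   attached as attribute `"sfs"`.
#' @export
gene_popgen <- function(gl, chrom_class = NULL, males_only = FALSE,
                        min_ind_fraction = 0.5, sfs = NULL) {
  if (males_only) {
    gl <- gl_subset(gl, individuals = which(gl$sex == "male"))
  }
  gl <- filter_sites(gl, min_ind_fraction)
  if (nrow(gl$L0) < 1) stop_invalid("no sites left after filtering")
  h <- saf_matrix(gl)
  fit <- if (is.null(sfs)) estimate_sfs_em(h) else sfs
  post <- site_posteriors(h, if (inherits(fit, "sfs_fit")) fit$sfs else fit)
  two_n <- ncol(h) - 1
  genes <- split(seq_len(nrow(post)), gl$sites$gene)
  out <- imap(genes, function(rows, g) {
    th <- gene_thetas(post[rows, , drop = FALSE])
    th$gene <- g
    th
  }) |> list_rbind()
  out <- out |>
    mutate(tajimas_d = map_dbl(seq_len(n()), function(i) {
      tajimas_d(out$theta_w[i], out$theta_pi[i], out$s_eff[i], two_n)
    })) |>
    select("gene", "n_sites", "s_eff", "theta_w", "theta_pi", "tajimas_d")
  out$chrom_class <- if (is.null(chrom_class)) NA_character_ else
    unname(chrom_class[out$gene])
  attr(out, "sfs") <- fit
  out
}
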