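# Population-genetic simulation: SFS shapes, Hardy-Weinberg genotypes with
# inbreeding, and read-depth/error-driven genotype likelihoods.

#' Simulate a site frequency spectrum shape
#'
#' Over segregating derived-allele counts `j = 1..two_n - 1`, probability
#' mass proportional to the neutral `1/j` weight times a balancing
#' "bump" factor `exp(-4 * strength * (j / two_n - 0.5)^2)` centered at
#' `j = two_n / 2`. With `strength = 0` this is the neutral spectrum;
#' large `strength` concentrates mass at intermediate frequency, which is
#' the balancing-selection signature Tajima's D responds to. The bump
#' factor itself is symmetric about `two_n / 2`; the neutral `1/j` weight
#' is not.
#'
#' @param two_n Chromosome count (>= 2).
#' @param strength Nonnegative bump strength.
#' @return Probability vector over `j = 1..two_n - 1`, summing to 1, of
#'   class `sfs_shape` with attribute `two_n`.
#' @export
#' @examples
#' simulate_sfs_shape(4, 0)   # (6, 3, 2) / 11
#' simulate_sfs_shape(10, 4)
simulate_sfs_shape <- function(two_n, strength) {
  if (two_n < 2) stop_invalid("`two_n` must be at least 2")
  if (strength < 0) stop_invalid("`strength` must be nonnegative")
  j <- seq_len(two_n - 1)
  w <- (1 / j) * exp(-4 * strength * (j / two_n - 0.5)^2)
  structure(normalize_sum1(w), two_n = two_n, class = "sfs_shape")
}

#' Simulate diploid genotypes with optional inbreeding
#'
#' Genotypes (copies of the derived allele) are drawn per site and
#' individual from the inbreeding-adjusted Hardy-Weinberg distribution:
#' `P(0) = (1-p)^2 + f p (1-p)`, `P(1) = 2 p (1-p) (1-f)`,
#' `P(2) = p^2 + f p (1-p)`.
#'
#' @param freqs Per-site derived-allele frequencies in (0, 1).
#' @param n_ind Number of individuals.
#' @param f Inbreeding coefficient in `[0, 1]`.
#' @param seed Integer seed.
#' @return Integer matrix (sites x individuals) of 0/1/2 genotypes.
#' @export
simulate_genotypes <- function(freqs, n_ind, f = 0, seed = 1) {
  p <- as.numeric(freqs)
  if (any(p <= 0 | p >= 1)) stop_invalid("frequencies must lie in (0, 1)")
  if (f < 0 || f > 1) stop_invalid("`f` must lie in [0, 1]")
  set.seed(derive_seed(seed, "genotypes"))
  p0 <- (1 - p)^2 + f * p * (1 - p)
  p1 <- 2 * p * (1 - p) * (1 - f)
  n_sites <- length(p)
  u <- matrix(runif(n_sites * n_ind), n_sites, n_ind)
  g <- matrix(0L, n_sites, n_ind)
  g[u >= p0] <- 1L
  g[u >= p0 + p1] <- 2L
  g
}

#' Simulate genotype likelihoods from read data
#'
#' Per individual-site, depth is Poisson(`mean_depth`) (a per-site depth
#' multiplier can emulate expression-coupled coverage), each read matches
#' the derived allele with probability
#' `(g/2)(1 - eps) + (1 - g/2)(eps/3)`, and the three normalized genotype
#' likelihoods follow the same per-read model as [genotype_likelihood].
#' Zero-depth sites get the flat triple and are flagged missing.
#'
#' @param genotypes Integer matrix (sites x individuals) of 0/1/2.
#' @param mean_depth Mean reads per site (>= 0).
#' @param error_rate Per-base error in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param sites Optional site tibble (`gene`, `pos`); defaults to one
#'   gene `"g1"` with consecutive positions.
#' @param sex Optional per-individual sex labels; defaults to an even
#'   male/female split.
#' @param depth_multiplier Optional per-site multiplier on `mean_depth`.
#' @return A [gl_table].
#' @export
simulate_genotype_likelihoods <- function(genotypes, mean_depth,
                                          error_rate, seed = 1,
                                          sites = NULL, sex = NULL,
                                          depth_multiplier = 1) {
  if (mean_depth < 0) stop_invalid("`mean_depth` must be nonnegative")
  if (error_rate < 0 || error_rate >= 0.5) {
    stop_invalid("`error_rate` must lie in [0, 0.5)")
  }
  g <- as.matrix(genotypes)
  n_sites <- nrow(g)
  n_ind <- ncol(g)
  set.seed(derive_seed(seed, "likelihoods"))
  mu <- mean_depth * rep_len(depth_multiplier, n_sites)
  d <- matrix(rpois(n_sites * n_ind, rep(mu, n_ind)), n_sites, n_ind)
  p_derived <- (g / 2) * (1 - error_rate) + (1 - g / 2) * (error_rate / 3)
  k <- matrix(rbinom(n_sites * n_ind, as.vector(d), as.vector(p_derived)),
              n_sites, n_ind)
  L <- gl_from_read_counts(k, d, error_rate)
  sites <- sites %||% tibble(gene = "g1", pos = seq_len(n_sites))
  sex <- sex %||% rep(c("male", "female"), length.out = n_ind)
  gl_table(L[[1]], L[[2]], L[[3]], sites, sex, missing = d == 0)
}

# Draw per-site population frequencies for one gene from an SFS shape;
# non-segregating sites are ancestral-fixed and reported as NA (they
# carry genotype 0 everywhere).
draw_site_freqs <- function(n_sites, shape, seg_fraction, pop_two_n) {
  seg <- runif(n_sites) < seg_fraction
  j <- sample(seq_len(pop_two_n - 1), sum(seg), replace = TRUE,
              prob = as.numeric(shape))
  out <- rep(NA_real_, n_sites)
  out[seg] <- j / pop_two_n
  out
}
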