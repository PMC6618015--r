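# Per-individual inbreeding coefficients by EM on genotype likelihoods.

#' Estimate per-individual inbreeding coefficients by EM
#'
#' Models each genotype as a mixture of an identical-by-descent component
#' (probability `F`: homozygous ancestral with probability `1 - p`,
#' homozygous derived with probability `p`) and a Hardy-Weinberg component
#' (probability `1 - F`). The E-step computes the posterior probability
#' that a site is IBD given the genotype likelihoods; the M-step sets `F`
#' to its mean over informative sites. `F` is clipped to `[0, 1]` and
#' iteration stops when `|delta F| < tol`.
#'
#' @param gl A [gl_table].
#' @param allele_freqs Per-site derived-allele frequencies in (0, 1).
#' @param tol Convergence tolerance on F (default 1e-6).
#' @param max_iter Maximum iterations (default 200).
#' @return Tibble with one row per individual: `individual`, `f`,
#'   `iterations`, `converged`.
#' @export
estimate_inbreeding_em <- function(gl, allele_freqs, tol = 1e-6,
                                   max_iter = 200) {
  p <- as.numeric(allele_freqs)
  if (length(p) != nrow(gl$L0)) {
    stop_invalid("`allele_freqs` must have one value per site")
  }
  if (any(p <= 0 | p >= 1)) stop_invalid("allele frequencies must be in (0, 1)")
  hwe0 <- (1 - p)^2
  hwe1 <- 2 * p * (1 - p)
  hwe2 <- p^2
  n_ind <- ncol(gl$L0)
  res <- map(seq_len(n_ind), function(i) {
    keep <- !gl$missing[, i]
    L0 <- gl$L0[keep, i]; L1 <- gl$L1[keep, i]; L2 <- gl$L2[keep, i]
    pk <- p[keep]
    if (length(L0) == 0) {
      return(tibble(individual = i, f = NA_real_, iterations = 0L,
                    converged = NA))
    }
    f <- 0.5
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      num <- f * (L0 * (1 - pk) + L2 * pk)
      den <- num + (1 - f) * (L0 * hwe0[keep] + L1 * hwe1[keep] +
                                L2 * hwe2[keep])
      z <- ifelse(den > 0, num / den, f)
      f_new <- min(max(mean(z), 0), 1)
      if (abs(f_new - f) < tol) {
        f <- f_new
        converged <- TRUE
        break
      }
      f <- f_new
    }
    tibble(individual = i, f = f, iterations = iter, converged = converged)
  })
  list_rbind(res)
}
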