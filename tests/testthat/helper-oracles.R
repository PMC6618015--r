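# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, textbook formulas and
# step-by-step recipes.

# SAF likelihood by full enumeration of genotype configurations (N <= 3).
oracle_saf_enum <- function(triples) {
  triples <- matrix(as.numeric(triples), ncol = 3)
  n <- nrow(triples)
  two_n <- 2 * n
  configs <- expand.grid(rep(list(0:2), n))
  h <- numeric(two_n + 1)
  for (r in seq_len(nrow(configs))) {
    g <- as.numeric(configs[r, ])
    w <- prod(vapply(seq_len(n), function(i) {
      triples[i, g[i] + 1] * choose(2, g[i])
    }, numeric(1)))
    j <- sum(g)
    h[j + 1] <- h[j + 1] + w
  }
  h <- h / choose(two_n, 0:two_n)
  h / max(h)
}

# Textbook Tajima's D from a hard genotype matrix (sites x individuals).
oracle_tajima_from_genotypes <- function(geno) {
  two_n <- 2 * ncol(geno)
  cnt <- rowSums(geno)
  seg <- cnt > 0 & cnt < two_n
  s <- sum(seg)
  if (s == 0) return(list(theta_w = 0, theta_pi = 0, d = NA_real_))
  n <- two_n
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_pi <- sum(cnt[seg] * (n - cnt[seg])) / choose(n, 2)
  theta_w <- s / a1
  d <- (theta_pi - theta_w) / sqrt(e1 * s + e2 * s * (s - 1))
  list(theta_w = theta_w, theta_pi = theta_pi, d = d)
}

# Exact (one-hot) genotype-likelihood table from a genotype matrix:
# error-free, deep-coverage hard calls.
onehot_gl <- function(geno, sites = NULL, sex = NULL) {
  L0 <- (geno == 0) * 1
  L1 <- (geno == 1) * 1
  L2 <- (geno == 2) * 1
  sites <- sites %||% tibble::tibble(gene = "g1", pos = seq_len(nrow(geno)))
  sex <- sex %||% rep(c("male", "female"), length.out = ncol(geno))
  gl_table(L0, L1, L2, sites, sex,
           missing = matrix(FALSE, nrow(geno), ncol(geno)))
}

# Step-by-step TMM recipe: reference by upper quartile, 30% trim on M,
# 5% on A, precision-weighted mean of M, geometric-mean-1 rescaling.
oracle_tmm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(i) {
    quantile(counts[, i], 0.75) / lib[i]
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(i) {
    obs <- counts[, i]; nO <- lib[i]
    rf <- counts[, ref]; nR <- lib[ref]
    logR <- log2((obs / nO) / (rf / nR))
    absE <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f / exp(mean(log(f)))
}

# small gl_table from explicit triples: list of N x 3 matrices, one per site
gl_from_triples <- function(site_triples, sex = NULL) {
  n_ind <- nrow(site_triples[[1]])
  L <- lapply(1:3, function(k) {
    do.call(rbind, lapply(site_triples, function(m) m[, k]))
  })
  sex <- sex %||% rep(c("male", "female"), length.out = n_ind)
  gl_table(L[[1]], L[[2]], L[[3]],
           tibble::tibble(gene = "g1", pos = seq_along(site_triples)),
           sex, missing = matrix(FALSE, length(site_triples), n_ind))
}
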