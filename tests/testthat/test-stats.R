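# Gene-class statistics: relative D, Wilcoxon contrasts, covariate
# regression, polynomial fits, top-quantile flags, permutation enrichment
# and the Z subsampling test.

test_that("relative Tajima's D is the difference of class medians", {
  expect_equal(relative_tajimas_d(c(-0.5, -0.5, -0.5), c(0.3, 0.3)), -0.8)
  expect_equal(relative_tajimas_d(c(1, 2), c(1, 2)), 0)
  expect_equal(relative_tajimas_d(c(1, 2, 9), c(0, 0, 4)), 2)
  expect_error(relative_tajimas_d(numeric(0), 1), "non-empty")
})

test_that("Wilcoxon contrast reproduces exact enumeration and detects
           large shifts", {
  same <- wilcoxon_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  out <- wilcoxon_contrast(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p_value, 0.1, tolerance = 1e-12)  # 2 * 1/20

  set.seed(5)
  big <- wilcoxon_contrast(rnorm(200, 1), rnorm(200, 0))
  expect_lt(big$p_value, 1e-6)
})

fake_gene_table <- function(n, beta_bias = 0, noise = 0.2, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    tissue_class = sample(c("gonad-biased", "non-tissue-biased"), n,
                          replace = TRUE),
    theta_w = runif(n, 0.5, 3),
    length_bp = round(runif(n, 300, 4000)),
    gc_fraction = runif(n, 0.3, 0.7),
    mean_expr = runif(n, 1, 400)
  ) |>
    dplyr::mutate(tajimas_d = beta_bias * (tissue_class == "gonad-biased") +
                    0.5 * log(theta_w) - 0.2 * log(length_bp) +
                    rnorm(n, 0, noise))
}

test_that("covariate regression recovers planted coefficients and flags
           degenerate designs", {
  # noiseless planted model is recovered exactly
  tbl <- fake_gene_table(60, beta_bias = -0.7, noise = 0, seed = 2)
  out <- suppressWarnings(covariate_regression(tbl))  # perfect fit
  expect_equal(out$estimate[out$term == "tissue_classgonad-biased"], -0.7,
               tolerance = 1e-8)
  expect_equal(out$estimate[out$term == "log_tw"], 0.5, tolerance = 1e-8)

  const <- tbl |> dplyr::mutate(tissue_class = "gonad-biased")
  expect_error(covariate_regression(const), "tissue_class")

  # matches the closed-form least-squares solution
  tbl2 <- fake_gene_table(50, beta_bias = -0.4, noise = 0.3, seed = 3)
  out2 <- covariate_regression(tbl2)
  df <- tbl2 |> dplyr::mutate(
    bias = as.numeric(tissue_class == "gonad-biased"),
    ltw = log(theta_w), llen = log(length_bp), lgc = log(gc_fraction),
    lex = log(mean_expr))
  X <- cbind(1, df$bias, df$ltw, df$llen, df$lgc, df$lex)
  beta_hat <- solve(t(X) %*% X, t(X) %*% df$tajimas_d)
  expect_equal(unname(out2$estimate), as.numeric(beta_hat),
               tolerance = 1e-10)
})

test_that("a planted tissue-bias effect stays significant across nuisance
           covariates", {
  sig <- vapply(1:50, function(r) {
    tbl <- fake_gene_table(80, beta_bias = -0.6, noise = 0.4,
                           seed = 500 + r)
    out <- covariate_regression(tbl)
    out$p_value[out$term == "tissue_classgonad-biased"] < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("polynomial sex-bias fits behave on exact, null and noisy
           quadratics", {
  x <- seq(-3, 3, length.out = 40)
  y <- 1 - 0.5 * x + 0.25 * x^2
  fit <- suppressWarnings(polynomial_sexbias_fit(y, x, degree = 2))
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate, c(1, -0.5, 0.25),
               tolerance = 1e-8)

  set.seed(7)
  r2 <- vapply(1:10, function(i) {
    polynomial_sexbias_fit(rnorm(1000), rnorm(1000), 2)$r_squared
  }, numeric(1))
  expect_lt(median(r2), 0.02)

  set.seed(8)
  yn <- 1 - 0.5 * x + 0.25 * x^2 + rnorm(40, 0, 0.3)
  fitn <- polynomial_sexbias_fit(yn, x, 2)
  expect_true(all(abs(fitn$coefficients$estimate - c(1, -0.5, 0.25)) <
                    2 * fitn$coefficients$std_error +
                    2 * c(0.3, 0.3, 0.3)))
  expect_error(polynomial_sexbias_fit(1:3, 1:3, 4), "degree")
})

test_that("top-quantile flags match an independent quantile computation", {
  d <- tibble::tibble(species = "sp1", orthogroup = paste0("og", 1:10),
                      tajimas_d = 1:10)
  out <- flag_top_quantile(d, 0.1)
  expect_equal(sum(out$top_flag), 1)
  expect_true(out$top_flag[out$tajimas_d == 10])

  ties <- d |> dplyr::mutate(tajimas_d = 2)
  expect_true(all(flag_top_quantile(ties, 0.1)$top_flag))

  set.seed(9)
  big <- tibble::tibble(species = "sp1", orthogroup = paste0("og", 1:100),
                        tajimas_d = rnorm(100))
  out2 <- flag_top_quantile(big, 0.1)
  thr <- quantile(big$tajimas_d, 0.9, type = 7)
  expect_equal(out2$top_flag, big$tajimas_d >= thr)
})

test_that("permutation enrichment has unit p-values in degenerate cases
           and tracks the hypergeometric tail", {
  genes <- paste0("og", 1:10)
  universal <- genes[1:2]
  full <- permutation_enrichment(universal, genes, genes, n_perm = 200,
                                 seed = 1)
  expect_equal(full$observed, 2)
  expect_equal(full$empirical_p, 1)

  none <- permutation_enrichment(character(0), genes[1:5], genes,
                                 n_perm = 200, seed = 2)
  expect_equal(none$observed, 0)
  expect_equal(none$empirical_p, 1)

  out <- permutation_enrichment(universal, genes[1:5], genes,
                                n_perm = 10000, seed = 3)
  p_true <- 56 / 252  # P(X >= 2), hypergeometric
  mc_se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(out$empirical_p_upper - p_true), 3 * mc_se + 2 / 10001)
  expect_error(permutation_enrichment(universal, character(0), genes,
                                      n_perm = 200), "empty")
})

test_that("Z subsampling test is exact in the degenerate copy case and
           rejects degenerate traits", {
  set.seed(10)
  sp <- paste0("sp", 1:4)
  auto <- purrr::map(sp, function(s) {
    tibble::tibble(species = s,
                   tajimas_d = c(rnorm(8, 1), rnorm(12, 0)),
                   class = rep(c("focal", "background"), c(8, 12)))
  }) |> purrr::list_rbind()
  z <- auto |> dplyr::filter(class == "focal") |>
    dplyr::select(species, tajimas_d)
  traits <- tibble::tibble(species = sp, trait = c(1, 2, 3, 4))
  out <- z_subsampling_test(auto, z, traits, n_rep = 100, seed = 11)
  expect_equal(out$p_r, 1)      # every replicate equals the observed value
  expect_equal(out$p_slope, 1)

  expect_error(
    z_subsampling_test(auto, z, traits |> dplyr::mutate(trait = 1),
                       n_rep = 50),
    "constant")
  z_big <- dplyr::bind_rows(z, z, z)
  expect_error(z_subsampling_test(auto, z_big, traits, n_rep = 50),
               "exceeds")
})

test_that("planted autosomal trait correlation with noise Z genes yields a
           small one-sided p", {
  hits <- vapply(1:6, function(r) {
    set.seed(400 + r)
    sp <- paste0("sp", 1:6)
    trait <- seq(-1, 1, length.out = 6)
    auto <- purrr::map2(sp, trait, function(s, tr) {
      tibble::tibble(species = s,
                     tajimas_d = c(rnorm(30, 1.5 * tr, 0.3),
                                   rnorm(40, 0, 0.3)),
                     class = rep(c("focal", "background"), c(30, 40)))
    }) |> purrr::list_rbind()
    z <- purrr::map(sp, function(s) {
      tibble::tibble(species = s, tajimas_d = rnorm(5, 0, 0.3))
    }) |> purrr::list_rbind()
    traits <- tibble::tibble(species = sp, trait = trait)
    out <- z_subsampling_test(auto, z, traits, n_rep = 400, seed = r)
    out$p_r < 0.1
  }, logical(1))
  expect_gte(sum(hits), 5)
})
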