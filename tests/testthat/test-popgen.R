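# Genotype likelihoods, SAF, SFS EM, thetas, Tajima's D, inbreeding EM and
# site filters.

test_that("per-read genotype likelihoods follow the mixture model", {
  expect_equal(genotype_likelihood(logical(0), 0.01), rep(1 / 3, 3))

  # one derived read, vanishing error: (0, 1/2, 1) normalized
  gl <- genotype_likelihood(TRUE, 1e-12)
  expect_equal(gl, c(0, 1 / 3, 2 / 3), tolerance = 1e-9)

  # two reads (1 derived, 1 ancestral), eps = 0.01: direct product
  eps <- 0.01
  direct <- vapply(0:2, function(g) {
    pd <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
    pd * (1 - pd)
  }, numeric(1))
  expect_equal(genotype_likelihood(c(TRUE, FALSE), eps),
               direct / sum(direct), tolerance = 1e-12)
  expect_error(genotype_likelihood(TRUE, 0.7), "0.5")
})

test_that("SAF likelihood matches hand cases and full enumeration", {
  expect_equal(saf_likelihood(matrix(c(1, 0, 0), 1)), c(1, 0, 0))
  # flat triple, N = 1: (1, 2, 1)/C(2, j) is uniform
  expect_equal(saf_likelihood(matrix(rep(1 / 3, 3), 1)), c(1, 1, 1))

  set.seed(77)
  for (n_ind in 1:3) {
    for (rep in 1:10) {
      tri <- matrix(runif(3 * n_ind), n_ind, 3)
      expect_equal(saf_likelihood(tri), oracle_saf_enum(tri),
                   tolerance = 1e-12)
    }
  }
  expect_error(saf_likelihood(matrix(numeric(0), 0, 3)), "no informative")
})

test_that("SFS EM handles perfect and uninformative data and has a
           monotone log-likelihood", {
  onehot <- matrix(0, 20, 5)
  onehot[, 2] <- 1
  fit <- estimate_sfs_em(onehot)
  expect_equal(fit$sfs, c(0, 1, 0, 0, 0), tolerance = 1e-9)

  flat <- matrix(1, 30, 5)
  fit_flat <- estimate_sfs_em(flat)
  expect_equal(fit_flat$sfs, rep(1 / 5, 5), tolerance = 1e-12)

  set.seed(12)
  noisy <- matrix(runif(400), 80, 5)
  fit_n <- suppressWarnings(estimate_sfs_em(noisy))
  expect_true(all(diff(fit_n$loglik) >= -1e-10))
  expect_equal(sum(fit_n$sfs), 1, tolerance = 1e-9)

  # the seeded sampling initialization reaches the same optimum here
  fit_s <- suppressWarnings(estimate_sfs_em(noisy, init = "sample",
                                            seed = 2))
  expect_lt(max(abs(fit_s$sfs - fit_n$sfs)), 1e-3)
  expect_true(all(diff(fit_s$loglik) >= -1e-10))
})

test_that("site posteriors combine SAF and prior correctly", {
  onehot <- matrix(c(0, 0, 1, 0, 0), 1)
  prior <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  expect_equal(as.numeric(site_posteriors(onehot, prior)),
               c(0, 0, 1, 0, 0))
  flat <- matrix(1, 1, 5)
  prior2 <- c(0.4, 0.3, 0.2, 0.05, 0.05)
  expect_equal(as.numeric(site_posteriors(flat, prior2)), prior2)
  mixed <- matrix(c(0.5, 1, 0.25, 0.1, 0), 1)
  hand <- mixed[1, ] * prior2 / sum(mixed[1, ] * prior2)
  expect_equal(as.numeric(site_posteriors(mixed, prior2)), hand)
})

test_that("gene thetas match closed forms", {
  # one-hot at j = 2, 2N = 4
  p <- matrix(c(0, 0, 1, 0, 0), 1)
  th <- gene_thetas(p)
  expect_equal(th$theta_pi, 2 * 2 / 6, tolerance = 1e-12)
  expect_equal(th$theta_w, 1 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)

  mono <- matrix(c(1, 0, 0, 0, 0), 1)
  th0 <- gene_thetas(mono)
  expect_equal(th0$theta_pi, 0)
  expect_equal(th0$theta_w, 0)

  half <- matrix(c(0.5, 0, 0.5, 0, 0), 1)
  th2 <- gene_thetas(half)
  expect_equal(th2$s_eff, 0.5)
  expect_equal(th2$theta_w, 0.5 / (11 / 6), tolerance = 1e-12)
  expect_equal(th2$theta_pi, 0.5 * 4 / 6, tolerance = 1e-12)
})

test_that("Tajima's D vanishes when estimators agree and is missing
           without segregating sites", {
  expect_equal(tajimas_d(1.3, 1.3, 5, 10), 0)
  expect_true(is.na(tajimas_d(0, 0, 0, 10)))
  expect_error(tajimas_d(1, 1, 1, 2), "two_n")
})

test_that("pipeline Tajima's D equals the textbook estimator on
           hard-called genotypes", {
  set.seed(31)
  n_genes <- 12
  sites <- 40
  freqs <- runif(n_genes * sites, 0.05, 0.95)
  geno <- simulate_genotypes(freqs, 8, seed = 32)
  site_info <- tibble::tibble(gene = rep(sprintf("g%02d", 1:n_genes),
                                         each = sites),
                              pos = rep(1:sites, n_genes))
  gl <- onehot_gl(geno, sites = site_info)
  pg <- gene_popgen(gl)
  for (g in unique(site_info$gene)) {
    rows <- which(site_info$gene == g)
    oracle <- oracle_tajima_from_genotypes(geno[rows, , drop = FALSE])
    got <- pg[pg$gene == g, ]
    expect_equal(got$theta_w, oracle$theta_w, tolerance = 1e-6)
    expect_equal(got$theta_pi, oracle$theta_pi, tolerance = 1e-6)
    expect_equal(got$tajimas_d, oracle$d, tolerance = 1e-6)
  }
})

test_that("site filter drops sites with data in fewer than half the
           individuals, overall or per sex", {
  tri_ok <- matrix(rep(c(1, 0, 0), each = 10), 10, 3)
  make_gl <- function(miss_pattern) {
    L0 <- matrix(1, 2, 10); L1 <- matrix(0, 2, 10); L2 <- matrix(0, 2, 10)
    gl_table(L0, L1, L2, tibble::tibble(gene = "g1", pos = 1:2),
             rep(c("male", "female"), each = 5), missing = miss_pattern)
  }
  # site 1: 5/10 informative -> retained; site 2: all missing -> dropped
  miss <- rbind(c(rep(FALSE, 5), rep(TRUE, 5)), rep(TRUE, 10))
  out <- filter_sites(make_gl(miss))
  expect_equal(nrow(out$L0), 1)

  # per-sex: 5/5 males but 1/5 females -> dropped
  miss2 <- rbind(c(rep(FALSE, 5), FALSE, rep(TRUE, 4)), rep(FALSE, 10))
  out2 <- filter_sites(make_gl(miss2), per_sex = TRUE)
  expect_equal(nrow(out2$L0), 1)
  out2b <- filter_sites(make_gl(miss2), per_sex = FALSE)
  expect_equal(nrow(out2b$L0), 2)
})

test_that("Z-chromosome mode uses male samples only", {
  set.seed(41)
  geno <- simulate_genotypes(runif(30, 0.2, 0.8), 10, seed = 42)
  gl <- onehot_gl(geno, sex = rep(c("male", "female"), each = 5))
  pg <- gene_popgen(gl, males_only = TRUE)
  # SFS support reflects 2N = 10 chromosomes from the 5 males
  expect_equal(length(attr(pg, "sfs")$sfs), 11)
})

test_that("inbreeding EM hits its bounds on certain genotypes and
           recovers a planted F", {
  p <- rep(0.5, 400)
  het <- matrix(1L, 400, 1)
  gl_het <- onehot_gl(het, sites = tibble::tibble(gene = "g1", pos = 1:400),
                      sex = "male")
  f_het <- estimate_inbreeding_em(gl_het, p)
  expect_lt(f_het$f, 1e-4)

  hom <- matrix(rep(c(0L, 2L), 200), 400, 1)
  gl_hom <- onehot_gl(hom, sites = tibble::tibble(gene = "g1", pos = 1:400),
                      sex = "male")
  f_hom <- estimate_inbreeding_em(gl_hom, p)
  expect_gt(f_hom$f, 1 - 1e-4)

  set.seed(54)
  freqs <- runif(1000, 0.1, 0.9)
  geno <- simulate_genotypes(freqs, 4, f = 0.3, seed = 55)
  gl <- simulate_genotype_likelihoods(geno, mean_depth = 30,
                                      error_rate = 0.005, seed = 56)
  fhat <- estimate_inbreeding_em(gl, freqs)
  expect_true(all(abs(fhat$f - 0.3) < 0.05))
})

test_that("neutral simulation gives near-zero mean per-gene D", {
  cfg <- sim_config(n_genes = 200, sites_per_gene = 40,
                    balancing_strength = 0, frac_gonad_biased = 0,
                    frac_spleen_biased = 0, frac_z_linked = 0, seed = 61)
  b <- simulate_species_dataset(cfg, focal_strength = 0,
                                background_strength = 0)
  pg <- gene_popgen(b$gl)
  expect_lt(abs(mean(pg$tajimas_d, na.rm = TRUE)), 0.3)
})
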