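test_that("identical configs give bit-identical cohorts", {
  cfg <- sim_config(n_individuals = 500, n_snps = 10, seed = 42,
                    outcome_kind = "binary", binary_prevalence = 0.1)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$covariates, b$covariates)
})

test_that("genotype dosages follow Hardy-Weinberg at their MAFs", {
  cfg <- sim_config(n_individuals = 50000, n_snps = 72, seed = 7)
  g <- simulate_genotypes(cfg)
  maf <- attr(g, "maf")
  freq <- colMeans(g) / 2
  se <- sqrt(maf * (1 - maf) / (2 * nrow(g)))
  expect_true(all(abs(freq - maf) < 3 * se))
  # MAF 0.5 symmetry: column mean near 1
  cfg2 <- sim_config(n_individuals = 50000, n_snps = 5,
                     maf_range = c(0.5, 0.5), seed = 8)
  g2 <- simulate_genotypes(cfg2)
  expect_true(all(abs(colMeans(g2) - 1) < 3 * sqrt(0.5 / nrow(g2))))
})

test_that("invalid configurations are rejected with messages", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(exposure_h2 = 1), "exposure_h2")
  expect_error(sim_config(exposure_h2 = 0.5,
                          confounder_effect_exposure = 0.8), "residual")
  expect_error(sim_config(binary_prevalence = 0), "prevalence")
  expect_error(sim_config(n_snps = 1), "n_snps")
})

test_that("exposure heritability is calibrated to exposure_h2", {
  cfg <- sim_config(n_individuals = 100000, n_snps = 72,
                    exposure_h2 = 0.016, seed = 3)
  g <- simulate_genotypes(cfg)
  ex <- simulate_exposure(g, cfg)
  score <- drop(g %*% ex$gamma)
  r2 <- summary(lm(ex$exposure ~ score))$r.squared
  expect_gt(r2, 0.012)
  expect_lt(r2, 0.020)
  expect_equal(mean(ex$exposure), 0, tolerance = 1e-10)
  expect_equal(sd(ex$exposure), 1, tolerance = 1e-10)
})

test_that("h2 = 0 removes all genetic effects on the exposure", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 10, exposure_h2 = 0,
                    seed = 4)
  g <- simulate_genotypes(cfg)
  ex <- simulate_exposure(g, cfg)
  expect_identical(ex$gamma, rep(0, 10))
  expect_lt(max(abs(cor(ex$exposure, g))), 3 / sqrt(nrow(g)) + 0.01)
})

test_that("no confounder path means no exposure-confounder correlation", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 5,
                    confounder_effect_exposure = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  ex <- simulate_exposure(g, cfg)
  expect_lt(abs(cor(ex$exposure, ex$confounder)), 3 / sqrt(nrow(g)))
})

test_that("binary outcome prevalence matches the target at biobank scale", {
  cfg <- sim_config(n_individuals = 145668, n_snps = 20,
                    outcome_kind = "binary", binary_prevalence = 0.018,
                    causal_coef = 0.405, seed = 6)
  coh <- simulate_cohort(cfg)
  prev <- mean(coh$outcomes$y)
  se <- sqrt(0.018 * 0.982 / cfg$n_individuals)
  expect_lt(abs(prev - 0.018), 3 * se)
})

test_that("a fully null outcome is independent of the genotypes", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 72, causal_coef = 0,
                    confounder_effect_outcome = 0, seed = 9)
  coh <- simulate_cohort(cfg)
  scan <- adipomr:::linear_scan(coh$genotypes, coh$outcomes$y)
  # p-values uniform: rejection rate near 5%
  expect_lt(abs(mean(scan$p < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 72) + 0.02)
})

test_that("quadratic causal shape gives zero linear but positive quadratic association", {
  cfg <- sim_config(n_individuals = 50000, n_snps = 5,
                    causal_function = "quadratic", causal_coef = 0.5,
                    confounder_effect_exposure = 0,
                    confounder_effect_outcome = 0, seed = 10)
  coh <- simulate_cohort(cfg)
  x <- coh$exposure
  y <- coh$outcomes$y
  expect_lt(abs(cor(y, x)), 0.02)
  expect_gt(cor(y, x^2), 0.1)
})

test_that("vectorized association scans agree with lm and glm", {
  set.seed(11)
  n <- 400
  G <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  y <- rnorm(n, 0.2 * G[, 1])
  ls <- adipomr:::linear_scan(G, y)
  for (j in 1:4) {
    co <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(ls$beta[j], co[2, 1], tolerance = 1e-10)
    expect_equal(ls$se[j], co[2, 2], tolerance = 1e-10)
    expect_equal(ls$p[j], co[2, 4], tolerance = 1e-8)
  }
  yb <- rbinom(n, 1, plogis(-1 + 0.3 * G[, 2]))
  lg <- adipomr:::logistic_scan(G, yb)
  for (j in 1:4) {
    co <- summary(glm(yb ~ G[, j], family = binomial()))$coefficients
    expect_equal(lg$beta[j], co[2, 1], tolerance = 1e-6)
    expect_equal(lg$se[j], co[2, 2], tolerance = 1e-6)
  }
})

test_that("summary statistics recover per-SNP exposure effects", {
  z <- numeric(0)
  for (seed in 12:14) {
    cfg <- sim_config(n_individuals = 20000, n_snps = 72, seed = seed)
    coh <- simulate_cohort(cfg)
    ss <- cohort_to_summary_stats(coh, "y", split = 0.5)
    if (seed == 12) {
      expect_s3_class(ss, "summary_stats")
      expect_true(all(ss$se_exposure > 0))
      expect_true(all(ss$se_outcome > 0))
      expect_equal(ss$n_exposure[1] + ss$n_outcome[1], 20000)
    }
    z <- c(z, abs(ss$beta_exposure - coh$truth$gamma) / ss$se_exposure)
  }
  expect_gte(mean(z < 3), 0.99)
})

test_that("a noiseless single-SNP exposure yields the exact per-allele beta", {
  set.seed(13)
  g <- cbind(rbinom(200, 2, 0.4), rbinom(200, 2, 0.4))
  x <- 0.37 * g[, 1]
  coh <- make_fake_cohort(g, x, list(y = rnorm(200)), gamma = c(0.37, 0))
  ss <- cohort_to_summary_stats(coh, "y", split = 0.5, seed = 1)
  expect_equal(ss$beta_exposure[1], 0.37, tolerance = 1e-12)
})

test_that("split must be a strict fraction and outcome must exist", {
  coh <- simulate_cohort(sim_config(n_individuals = 200, n_snps = 3,
                                    seed = 14))
  expect_error(cohort_to_summary_stats(coh, "y", split = 0), "split")
  expect_error(cohort_to_summary_stats(coh, "y", split = 1), "split")
  expect_error(cohort_to_summary_stats(coh, "nope"), "outcome")
})

test_that("direct summary-level simulation controls pleiotropy as configured", {
  s0 <- simulate_summary_stats(n_snps = 50, theta = 0.2, seed = 20)
  expect_identical(attr(s0, "alpha"), rep(0, 50))
  s1 <- simulate_summary_stats(n_snps = 50, theta = 0.2,
                               pleiotropy_mode = "directional",
                               pleiotropy_mean = 0.05,
                               pleiotropy_sd = 0.01, n_invalid = 20,
                               seed = 21)
  expect_true(all(attr(s1, "alpha")[21:50] == 0))
  expect_true(all(attr(s1, "alpha")[1:20] != 0))
  s2 <- simulate_summary_stats(n_snps = 50, pleiotropy_mode = "inside_violating",
                               inside_rho = 0.8, pleiotropy_sd = 1e-6,
                               seed = 22)
  expect_gt(cor(attr(s2, "alpha"), attr(s2, "gamma")), 0.99)
})
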