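test_that("single-instrument linear 2SLS equals the covariance IV ratio", {
  set.seed(1)
  n <- 800
  g <- rbinom(n, 2, 0.3)
  u <- rnorm(n)
  x <- 0.2 * g + 0.5 * u + rnorm(n)
  y <- 0.3 * x + 0.5 * u + rnorm(n)
  coh <- make_fake_cohort(cbind(g, rbinom(n, 2, 0.3)), x, list(y = y))
  est <- tsls(coh, "y", grs = g)
  expect_equal(est$beta, cov(g, y) / cov(g, x), tolerance = 1e-12)
})

test_that("2SLS is invariant to affine rescaling of the instrument", {
  set.seed(2)
  cfg <- sim_config(n_individuals = 3000, n_snps = 10, seed = 2)
  coh <- simulate_cohort(cfg)
  s <- cohort_grs(coh)
  e1 <- tsls(coh, "y", grs = as.numeric(s))
  e2 <- tsls(coh, "y", grs = as.numeric(3.7 * s - 2))
  expect_equal(e1$beta, e2$beta, tolerance = 1e-10)
  expect_equal(e1$se, e2$se, tolerance = 1e-10)
})

test_that("2SLS recovers the causal slope under confounding", {
  est <- obs <- numeric(30)
  for (r in 1:30) {
    cfg <- sim_config(n_individuals = 5000, n_snps = 30,
                      exposure_h2 = 0.05, causal_coef = 0.1,
                      confounder_effect_exposure = 0.5,
                      confounder_effect_outcome = 0.5, seed = 100 + r)
    coh <- simulate_cohort(cfg)
    est[r] <- tsls(coh, "y")$beta
    obs[r] <- fit_observational(coh, "y", covariates = character())$beta
  }
  expect_lt(abs(mean(est) - 0.1), 2 * mc_se(est))
  expect_gt(abs(mean(obs) - 0.1), 4 * mc_se(obs))  # biased away
})

test_that("null-cohort 2SLS confidence intervals cover zero at nominal rate", {
  cover <- logical(150)
  for (r in 1:150) {
    cfg <- sim_config(n_individuals = 2000, n_snps = 10,
                      exposure_h2 = 0.05, causal_coef = 0,
                      seed = 300 + r)
    coh <- simulate_cohort(cfg)
    e <- tsls(coh, "y")
    cover[r] <- e$ci_low <= 0 && 0 <= e$ci_high
  }
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.05 * 0.95 / 150))
})

test_that("binary 2SLS reports log-odds with a usable OR and counts", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 30,
                    exposure_h2 = 0.05, causal_coef = 0.4,
                    outcome_kind = "binary", binary_prevalence = 0.05,
                    seed = 4)
  coh <- simulate_cohort(cfg)
  est <- tsls(coh, "y")
  expect_match(est$scale, "log-odds")
  expect_gt(exp(est$beta), 0)
  expect_equal(est$n_cases + est$n_controls, 20000)
  # bootstrap SE is the same order as the analytic one
  eb <- tsls(coh, "y", se_method = "bootstrap", n_boot = 120, seed = 9)
  expect_lt(abs(log(eb$se / est$se)), log(3))
})

test_that("weak instruments attach a flag", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 5, exposure_h2 = 0.001,
                    seed = 5)
  coh <- simulate_cohort(cfg)
  est <- tsls(coh, "y")
  expect_true(any(grepl("weak_instrument", est$flags)))
})

test_that("sex-stratified estimates agree when there is no interaction", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 30,
                    exposure_h2 = 0.05, causal_coef = 0.2, sex_effect = 0,
                    seed = 6)
  coh <- simulate_cohort(cfg)
  em <- tsls(coh, "y", subset = coh$covariates$sex == 1)
  ef <- tsls(coh, "y", subset = coh$covariates$sex == 0)
  expect_lt(abs(em$beta - ef$beta), 2 * sqrt(em$se^2 + ef$se^2))
})

test_that("exclusion sensitivity: empty rule is a no-op, counts are logged", {
  cfg <- sim_config(n_individuals = 3000, n_snps = 10, seed = 7)
  coh <- simulate_cohort(cfg)
  full <- tsls(coh, "y")
  none <- run_exclusion_sensitivity(coh, rep(FALSE, 3000), outcome = "y")
  expect_equal(none$beta, full$beta, tolerance = 1e-12)
  expect_equal(none$exclusion, list(retained = 3000, excluded = 0))
  expect_error(run_exclusion_sensitivity(coh, rep(TRUE, 3000),
                                         outcome = "y"), "every individual")
})

test_that("excluding on a non-genetic medication flag barely moves the estimate", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 30,
                    exposure_h2 = 0.05, causal_coef = 0.3,
                    outcome_kind = "binary", binary_prevalence = 0.1,
                    seed = 8)
  coh <- simulate_cohort(cfg)
  set.seed(88)
  # medication correlates with the outcome but not with genotype
  coh$covariates$medication <-
    rbinom(20000, 1, plogis(-3 + 2 * coh$outcomes$y))
  full <- tsls(coh, "y")
  sub <- run_exclusion_sensitivity(coh, ~ medication == 1, outcome = "y")
  expect_lt(abs(sub$beta - full$beta), 2 * sqrt(sub$se^2 + full$se^2))
  # random 15% exclusion on a null cohort still covers zero
  cfg0 <- sim_config(n_individuals = 5000, n_snps = 20,
                     exposure_h2 = 0.05, causal_coef = 0, seed = 12)
  coh0 <- simulate_cohort(cfg0)
  set.seed(99)
  e0 <- run_exclusion_sensitivity(coh0, runif(5000) < 0.15, outcome = "y")
  expect_true(e0$ci_low <= 0 && 0 <= e0$ci_high)
})

test_that("case-subtype recoding partitions cases and keeps controls", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 30,
                    exposure_h2 = 0.05, causal_coef = 0.5,
                    outcome_kind = "binary", binary_prevalence = 0.1,
                    seed = 10)
  coh <- simulate_cohort(cfg)
  y <- coh$outcomes$y
  # subtype: cases in the top exposure decile (weight-gain-like proxy)
  rule <- coh$exposure > quantile(coh$exposure, 0.9)
  coh2 <- recode_case_subtype(coh, "y", rule)
  sub <- coh2$outcomes$y_subtype
  oth <- coh2$outcomes$y_other
  expect_true(all(which(sub == 1) != 0))
  expect_length(intersect(which(sub == 1), which(oth == 1)), 0)
  expect_equal(which(sub == 0), which(y == 0))
  expect_equal(sum(sub == 1, na.rm = TRUE) + sum(oth == 1, na.rm = TRUE),
               sum(y == 1))
  # exposure-dependent subtype amplifies the MR estimate
  es <- tsls(coh2, "y_subtype")
  eo <- tsls(coh2, "y_other")
  expect_gt(es$beta, eo$beta)
  # selecting all cases reproduces the original outcome
  coh3 <- recode_case_subtype(coh, "y", rep(TRUE, 20000))
  expect_equal(coh3$outcomes$y_subtype, y)
  expect_error(recode_case_subtype(coh, "y", rep(FALSE, 20000)),
               "zero cases")
})
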