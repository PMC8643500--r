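test_that("IV-free exposure is orthogonal to the instrument", {
  set.seed(1)
  n <- 2000
  g <- rnorm(n)
  x <- 0.2 * g + rnorm(n)
  res <- iv_free_exposure(x, g)
  expect_lt(abs(cov(res, g)), 1e-12)
  expect_equal(mean(res), mean(x), tolerance = 1e-12)
  # an instrument with exactly zero sample covariance leaves x untouched
  g_perp <- residuals(lm(g ~ x))
  expect_equal(iv_free_exposure(x, g_perp), x, tolerance = 1e-10)
  expect_error(iv_free_exposure(x, rep(1, n)), "zero-variance")
})

test_that("IV-free variance matches the h2 decomposition", {
  cfg <- sim_config(n_individuals = 50000, n_snps = 72,
                    exposure_h2 = 0.016, seed = 2)
  coh <- simulate_cohort(cfg)
  s <- cohort_grs(coh)
  res <- iv_free_exposure(coh$exposure, s)
  expect_equal(var(res), (1 - 0.016) * var(coh$exposure),
               tolerance = 0.005)
})

test_that("stratification gives equal counts with deterministic ties", {
  x <- rnorm(1000)
  st <- stratify_exposure(x, 10)
  expect_equal(unname(table(st)), rep(100L, 10), ignore_attr = TRUE)
  # ties broken by stable first-occurrence rank
  xt <- rep(c(1, 2), each = 10)
  st2 <- stratify_exposure(xt, 2)
  expect_identical(st2, rep(c(1L, 2L), each = 10))
  expect_identical(stratify_exposure(xt, 2), st2)
  expect_error(stratify_exposure(x, 0), "n_strata")
})

test_that("linear truth gives flat LACEs matching the global slope", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 72,
                    exposure_h2 = 0.016, causal_coef = 0.1, seed = 3)
  coh <- simulate_cohort(cfg)
  s <- cohort_grs(coh)
  nl <- mr_nonlinear(coh$exposure, coh$outcomes$y, s, n_boot = 50,
                     seed = 4)
  l <- nl$strata
  expect_equal(nrow(l), 10)
  expect_true(all(l$flag == ""))
  z <- abs(l$lace - 0.1) / l$se_lace
  expect_gte(sum(z < 2), 8)   # ~nominal per-stratum coverage
  expect_true(all(z < 4))
  # strata partition the sample
  expect_equal(sum(l$n), 20000)
  # under linearity the piecewise slope matches 2SLS within 2 SE
  iv <- tsls(coh, "y", grs = as.numeric(s))
  glob <- (nl$curve$values[11] - nl$curve$values[1]) /
    (nl$curve$knots[11] - nl$curve$knots[1])
  expect_lt(abs(glob - iv$beta), 2 * iv$se + 2 * mean(l$se_lace))
})

test_that("quadratic truth gives LACEs rising with stratum mean exposure", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 72,
                    exposure_h2 = 0.016, causal_function = "quadratic",
                    causal_coef = 0.3, seed = 5)
  coh <- simulate_cohort(cfg)
  s <- cohort_grs(coh)
  nl <- mr_nonlinear(coh$exposure, coh$outcomes$y, s, curve = FALSE)
  l <- nl$strata
  expect_gt(l$lace[10], l$lace[1])
  expect_gt(cor(l$lace, l$mean_exposure, method = "spearman"), 0.6)
  expect_lt(nl$tests$quadratic_test$p, 0.05)
})

test_that("LACE identity and curve continuity hold exactly", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 20,
                    exposure_h2 = 0.05, causal_coef = 0.2, seed = 6)
  coh <- simulate_cohort(cfg)
  s <- cohort_grs(coh)
  nl <- mr_nonlinear(coh$exposure, coh$outcomes$y, s, n_boot = 30,
                     seed = 7)
  l <- nl$strata
  expect_equal(l$lace * l$beta_iv_exposure, l$beta_iv_outcome,
               tolerance = 1e-12)
  cv <- nl$curve
  widths <- diff(cv$knots)
  expect_equal(diff(cv$values), l$lace * widths, tolerance = 1e-12)
  expect_equal(cv$values[1], 0)
  # equal slopes integrate to a straight line
  vals <- adipomr:::piecewise_values(rep(0.25, 10), cv$knots)
  expect_equal(vals, 0.25 * (cv$knots - cv$knots[1]), tolerance = 1e-12)
})

test_that("with one stratum the LACE is the whole-sample IV ratio", {
  set.seed(8)
  n <- 5000
  g <- rnorm(n)
  x <- 0.3 * g + rnorm(n)
  y <- 0.2 * x + rnorm(n)
  l <- lace_per_stratum(x, y, g, rep(1L, n))
  expect_equal(l$lace, cov(g, y) / cov(g, x), tolerance = 1e-10)
})

test_that("the curve shifts with the exposure but keeps its slopes", {
  set.seed(9)
  n <- 4000
  g <- rnorm(n)
  x <- 0.3 * g + rnorm(n)
  y <- 0.2 * x + rnorm(n)
  st <- stratify_exposure(iv_free_exposure(x, g), 5)
  l1 <- lace_per_stratum(x, y, g, st)
  l2 <- lace_per_stratum(x + 5, y, g, st)
  expect_equal(l2$lace, l1$lace, tolerance = 1e-10)
  expect_equal(l2$low, l1$low + 5, tolerance = 1e-10)
  expect_equal(l2$mean_exposure, l1$mean_exposure + 5, tolerance = 1e-10)
})

test_that("unstable strata are flagged and withheld", {
  set.seed(10)
  n <- 3000
  g <- rnorm(n)            # instrument unrelated to the exposure
  x <- rnorm(n)
  y <- rnorm(n)
  st <- stratify_exposure(x, 5)
  l <- lace_per_stratum(x, y, g, st, ivfree = x)
  expect_true(any(l$flag == "weak_denominator"))
  expect_true(all(is.na(l$lace[l$flag != ""])))
  # tiny strata are flagged too
  l2 <- lace_per_stratum(x[1:40], y[1:40], g[1:40], rep(1:2, 20),
                         ivfree = x[1:40])
  expect_true(all(l2$flag == "too_few_individuals"))
  # flagged strata break the piecewise chain with an informative error
  expect_error(piecewise_curve(x, y, g, st, n_boot = 10, seed = 1),
               "stratum")
})

test_that("non-linearity tests behave on degenerate and small inputs", {
  l <- data.frame(stratum = 1:4, low = 1:4, high = 2:5,
                  mean_exposure = 1:4 + 0.5, n = 100, n_cases = NA,
                  beta_iv_exposure = 1, beta_iv_outcome = 0.3,
                  lace = 0.3, se_lace = 0.1, flag = "")
  t0 <- nonlinearity_tests(l)
  expect_equal(t0$q_test$statistic, 0)
  expect_equal(t0$quadratic_test$slope, 0, tolerance = 1e-12)
  expect_error(nonlinearity_tests(l[1:2, ]), ">= 3")
})

test_that("binary outcomes produce log-odds LACEs with case guards", {
  cfg <- sim_config(n_individuals = 20000, n_snps = 30,
                    exposure_h2 = 0.05, causal_coef = 0.3,
                    outcome_kind = "binary", binary_prevalence = 0.1,
                    seed = 11)
  coh <- simulate_cohort(cfg)
  s <- cohort_grs(coh)
  nl <- mr_nonlinear(coh$exposure, coh$outcomes$y, s, curve = FALSE,
                     outcome_kind = "binary")
  expect_true(all(nl$strata$n_cases > 0))
  expect_true(all(is.finite(nl$strata$lace[nl$strata$flag == ""])))
})
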