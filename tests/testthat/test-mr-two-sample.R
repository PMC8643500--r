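test_that("Wald ratios follow the delta-method arithmetic", {
  h <- data.frame(SNP = c("a", "b", "c"),
                  beta_exposure = c(0.10, 0.10, 0),
                  se_exposure = 0.01,
                  beta_outcome = c(0.05, 0, 0.1),
                  se_outcome = c(0.02, 0.02, 0.02))
  r <- wald_ratios(h)
  expect_equal(r$theta, c(0.5, 0))
  expect_equal(r$se_theta, c(0.2, 0.2))
  expect_equal(r$weight, 1 / c(0.04, 0.04))
  ex <- attr(r, "excluded")
  expect_equal(ex$SNP, "c")
  expect_equal(ex$reason, "zero_exposure_beta")
  # second-order SE adds the exposure-side term
  r2 <- wald_ratios(h, second_order = TRUE)
  expect_true(all(r2$se_theta >= r$se_theta))
})

test_that("IVW matches hand arithmetic and collapses correctly", {
  r <- data.frame(theta = c(1, 3), se_theta = 1, weight = 1)
  est <- mr_ivw(r)
  expect_equal(est$beta, 2)
  expect_equal(est$heterogeneity$Q, 2)
  # multiplicative random effects: SE = sqrt(1/2) * sqrt(2/1)
  expect_equal(est$se, 1)
  # identical ratios: Q = 0 and the fixed-effect SE is kept
  r0 <- data.frame(theta = c(0.7, 0.7, 0.7), se_theta = c(1, 2, 0.5),
                   weight = 1 / c(1, 4, 0.25))
  e0 <- mr_ivw(r0)
  expect_equal(e0$beta, 0.7)
  expect_equal(e0$heterogeneity$Q, 0)
  expect_equal(e0$se, sqrt(1 / sum(r0$weight)))
  expect_error(mr_ivw(r[1, ]), "single Wald ratio")
  # the internal core with k = 1 degenerates to the Wald ratio itself
  core <- adipomr:::ivw_core(0.42, 25)
  expect_equal(core$beta, 0.42)
  expect_equal(core$se, sqrt(1 / 25))
})

test_that("fixed-effect IVW agrees with an independent meta-analysis fit", {
  set.seed(3)
  r <- data.frame(theta = rnorm(10, 0.2, 0.1),
                  se_theta = runif(10, 0.05, 0.2))
  r$weight <- 1 / r$se_theta^2
  core <- adipomr:::ivw_core(r$theta, r$weight)
  fe <- metafor::rma(yi = r$theta, sei = r$se_theta, method = "FE")
  expect_equal(core$beta, as.numeric(fe$beta), tolerance = 1e-10)
  expect_equal(core$se_fixed, fe$se, tolerance = 1e-10)
  expect_equal(core$Q, fe$QE, tolerance = 1e-10)
})

test_that("estimators are invariant to variant ordering", {
  s <- simulate_summary_stats(n_snps = 30, theta = 0.2, se_outcome = 0.03,
                              seed = 4)
  perm <- sample(30)
  sp <- s[perm, ]
  expect_equal(mr_ivw(wald_ratios(s))$beta,
               mr_ivw(wald_ratios(sp))$beta, tolerance = 1e-12)
  expect_equal(mr_egger(s)$beta, mr_egger(sp)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(s, n_boot = 100, seed = 1)$beta,
               mr_weighted_median(sp, n_boot = 100, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("MR-Egger recovers the slope under directional pleiotropy with InSIDE", {
  ivw_b <- egg_b <- egg_int <- numeric(100)
  for (r in 1:100) {
    s <- simulate_summary_stats(n_snps = 72, theta = 0.1,
                                pleiotropy_mode = "directional",
                                pleiotropy_mean = 0.05,
                                pleiotropy_sd = 0.03, seed = 1000 + r)
    ivw_b[r] <- mr_ivw(wald_ratios(s))$beta
    e <- mr_egger(s)
    egg_b[r] <- e$beta
    egg_int[r] <- e$intercept$value
  }
  expect_lt(abs(mean(egg_b) - 0.1), 2 * mc_se(egg_b))
  expect_gt(abs(mean(ivw_b) - 0.1), 4 * mc_se(ivw_b))  # IVW is biased
  expect_lt(abs(mean(egg_int) - 0.05), 2 * mc_se(egg_int))
})

test_that("Egger intercept test is roughly calibrated under balanced pleiotropy", {
  p <- numeric(400)
  for (r in 1:400) {
    s <- simulate_summary_stats(n_snps = 72, theta = 0.1,
                                pleiotropy_mode = "balanced",
                                pleiotropy_sd = 0.05, seed = 2000 + r)
    p[r] <- mr_egger(s)$intercept$p
  }
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
})

test_that("Egger needs 3 variants and flags a collinear design", {
  s <- simulate_summary_stats(n_snps = 5, seed = 5)
  expect_error(mr_egger(s[1:2, ]), ">= 3")
  s$beta_exposure <- 0.1
  e <- mr_egger(s)
  expect_true(any(grepl("collinear", e$flags)))
  expect_true(is.na(e$beta))
  # the degenerate fit collapses to the weighted mean of outcome betas
  w <- 1 / s$se_outcome^2
  expect_equal(e$intercept$value, sum(w * s$beta_outcome) / sum(w))
})

test_that("weighted median reduces to the plain median and obeys breakdown", {
  h <- data.frame(beta_exposure = c(1, 1, 1), se_exposure = 0.01,
                  beta_outcome = c(1, 2, 3), se_outcome = 1)
  expect_warning(
    est <- mr_weighted_median(h, n_boot = 50, seed = 1),
    "n_boot")
  expect_equal(est$beta, 2)
  # a dominant variant with the remaining weight split symmetrically
  wm <- adipomr:::weighted_median_estimate(c(1, 2, 3), c(0.2, 0.6, 0.2))
  expect_equal(wm, 2)
  wm2 <- adipomr:::weighted_median_estimate(c(5, 1, 9), c(0.7, 0.15, 0.15))
  expect_equal(wm2, 5)
})

test_that("penalization leaves homogeneous sets alone and downweights outliers", {
  th <- rep(0.2, 10)
  w <- rep(4, 10)
  expect_equal(adipomr:::penalize_weights(th, w), w)
  th2 <- c(rep(0.2, 9), 5)
  w2 <- adipomr:::penalize_weights(th2, w)
  expect_lt(w2[10], w[10])
  expect_equal(w2[1:9], w[1:9], tolerance = 1e-6)
})

test_that("penalized weighted median resists a single outlier better", {
  err_wm <- err_pwm <- numeric(60)
  for (r in 1:60) {
    s <- simulate_summary_stats(n_snps = 30, theta = 0.1, seed = 3000 + r)
    # a precise (hence heavily weighted) outlier that pulls the median
    s$beta_outcome[1] <- s$beta_outcome[1] + 0.5
    s$se_outcome[1] <- 0.012
    err_wm[r] <- abs(mr_weighted_median(s, n_boot = 100,
                                        seed = r)$beta - 0.1)
    err_pwm[r] <- abs(mr_penalized_weighted_median(s, n_boot = 100,
                                                   seed = r)$beta - 0.1)
  }
  expect_lte(mean(err_pwm), mean(err_wm) + 1e-6)
})

test_that("all four estimators agree when no pleiotropy is present", {
  s <- simulate_summary_stats(n_snps = 72, theta = 0.15, se_outcome = 0.03,
                              seed = 6)
  ests <- mr_two_sample_all(s, n_boot = 200, seed = 7)
  b <- vapply(ests, function(e) e$beta, numeric(1))
  se <- vapply(ests, function(e) e$se, numeric(1))
  for (i in seq_along(b)) for (j in seq_along(b)) {
    expect_lt(abs(b[i] - b[j]), 2 * sqrt(se[i]^2 + se[j]^2))
  }
})

test_that("Wald ratios are invariant to the harmonized orientation", {
  p <- make_stats_pair(k = 10, seed = 7)
  h <- harmonize(p$exposure, p$outcome)
  # flip a retained variant by hand: both betas negate together
  h2 <- h
  h2$beta_exposure[1] <- -h2$beta_exposure[1]
  h2$beta_outcome[1] <- -h2$beta_outcome[1]
  expect_equal(wald_ratios(h)$theta, wald_ratios(h2)$theta,
               tolerance = 1e-12)
})
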