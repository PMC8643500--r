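#' IV-free exposure: the non-genetic component of the exposure
#'
#' Residuals of the linear regression of the exposure on the instrument
#' (genetic risk score), re-centred by adding back the overall exposure
#' mean so stratum boundaries live on the exposure's own scale. Stratifying
#' on this quantity rather than on the exposure itself avoids collider
#' bias, because the residual is exactly orthogonal to the instrument.
#' Assumes a linear effect of the instrument on the exposure.
#'
#' @param exposure Exposure vector (raw or standardized scale).
#' @param grs Instrument vector.
#' @return Numeric vector, same scale as `exposure`.
#' @export
iv_free_exposure <- function(exposure, grs) {
  stopifnot(length(exposure) == length(grs))
  if (stats::sd(grs) == 0) stop("zero-variance instrument")
  fit <- stats::lm.fit(cbind(1, grs), exposure)
  fit$residuals + mean(exposure)
}

#' Equal-count quantile strata of the IV-free exposure
#'
#' Splits individuals into `n_strata` equal-count strata by rank of the
#' IV-free exposure (deciles by default, the pre-specified choice for
#' non-linear MR here). Ties are broken by stable first-occurrence rank, so
#' assignment is deterministic.
#'
#' @param ivfree IV-free exposure vector.
#' @param n_strata Number of strata (>= 2; default 10).
#' @return Integer vector of stratum indices in `1..n_strata`.
#' @export
stratify_exposure <- function(ivfree, n_strata = 10L) {
  if (n_strata < 1L) stop("n_strata must be >= 1")
  n <- length(ivfree)
  r <- rank(ivfree, ties.method = "first")
  as.integer(ceiling(r * n_strata / n))
}

#' Local average causal effects per stratum
#'
#' Within each stratum of the IV-free exposure, the LACE is the ratio of
#' the IV-outcome association to the IV-exposure association: the slope of
#' outcome on instrument (logistic regression for binary outcomes, so the
#' LACE is on the log-odds scale) divided by the slope of exposure on
#' instrument (linear). The standard error is first-order delta on the
#' numerator, `se_outcome_slope / |exposure_slope|`. Strata are flagged
#' (LACE withheld) when too small (< `min_n`), when a binary outcome has
#' fewer than `min_cases` cases, when a within-stratum fit fails, or when
#' the denominator slope is indistinguishable from zero (p > 0.05), which
#' makes the ratio unstable.
#'
#' @param exposure Exposure vector (the scale LACEs are per unit of).
#' @param outcome Outcome vector (0/1 or continuous).
#' @param grs Instrument vector.
#' @param strata Integer assignment from [stratify_exposure()].
#' @param ivfree IV-free exposure (for stratum ranges/means); defaults to
#'   recomputing from `exposure` and `grs`.
#' @param outcome_kind `"continuous"`, `"binary"` or NULL to infer.
#' @param min_n,min_cases Stability thresholds per stratum.
#' @return Data.frame with one row per stratum: `stratum`, `low`, `high`,
#'   `mean_exposure`, `n`, `n_cases`, `beta_iv_exposure`,
#'   `beta_iv_outcome`, `lace`, `se_lace`, `flag` ("" when usable).
#' @export
lace_per_stratum <- function(exposure, outcome, grs, strata,
                             ivfree = NULL, outcome_kind = NULL,
                             min_n = 30L, min_cases = 10L) {
  stopifnot(length(exposure) == length(outcome),
            length(grs) == length(outcome),
            length(strata) == length(outcome))
  if (is.null(ivfree)) ivfree <- iv_free_exposure(exposure, grs)
  if (is.null(outcome_kind)) {
    outcome_kind <- if (all(outcome %in% c(0, 1)) &&
                        length(unique(outcome)) == 2L) "binary"
                    else "continuous"
  }
  ids <- sort(unique(strata))
  rows <- lapply(ids, function(s) {
    i <- which(strata == s)
    n_s <- length(i)
    n_cases <- if (outcome_kind == "binary") sum(outcome[i] == 1)
               else NA_integer_
    row <- data.frame(stratum = s, low = min(ivfree[i]),
                      high = max(ivfree[i]),
                      mean_exposure = mean(ivfree[i]),
                      n = n_s, n_cases = n_cases,
                      beta_iv_exposure = NA_real_,
                      beta_iv_outcome = NA_real_,
                      lace = NA_real_, se_lace = NA_real_,
                      flag = "", stringsAsFactors = FALSE)
    if (n_s < min_n) { row$flag <- "too_few_individuals"; return(row) }
    if (outcome_kind == "binary" && n_cases < min_cases) {
      row$flag <- "too_few_cases"; return(row)
    }
    den <- simple_slope(grs[i], exposure[i])
    num <- if (outcome_kind == "binary") {
      tryCatch(logistic_slope(grs[i], outcome[i]),
               error = function(e) NULL)
    } else {
      simple_slope(grs[i], outcome[i])
    }
    if (is.null(num) || !is.finite(num$beta)) {
      row$flag <- "nonconvergent_fit"; return(row)
    }
    row$beta_iv_exposure <- den$beta
    row$beta_iv_outcome <- num$beta
    if (den$p > 0.05) { row$flag <- "weak_denominator"; return(row) }
    row$lace <- num$beta / den$beta
    row$se_lace <- num$se / abs(den$beta)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# closed-form simple linear regression slope of y on z
simple_slope <- function(z, y) {
  n <- length(z)
  zc <- z - mean(z)
  szz <- sum(zc^2)
  beta <- sum(zc * y) / szz
  resid <- y - mean(y) - beta * zc
  se <- sqrt(sum(resid^2) / (n - 2) / szz)
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(beta / se), n - 2))
}

logistic_slope <- function(z, y) {
  fit <- stats::glm.fit(cbind(1, z), y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-8,
                                                     maxit = 100))
  if (!fit$converged) stop("logistic fit did not converge")
  xw <- cbind(1, z) * sqrt(fit$weights)
  se <- sqrt(chol2inv(chol(crossprod(xw)))[2L, 2L])
  beta <- fit$coefficients[2L]
  list(beta = unname(beta), se = se, p = 2 * stats::pnorm(-abs(beta / se)))
}

# cumulative piecewise-linear curve from per-stratum slopes; knots are the
# stratum boundaries, the curve is 0 at the first knot and each segment
# starts where the previous ended
piecewise_values <- function(lace, knots) {
  widths <- diff(knots)
  c(0, cumsum(lace * widths))
}

#' Continuity-constrained piecewise-linear causal curve
#'
#' Integrates the per-stratum LACE slopes into one continuous curve of the
#' causal effect of the exposure: within each stratum the curve is linear
#' with slope equal to that stratum's LACE, each segment beginning where
#' the previous one ended, referenced to 0 at the first knot. Knots are the
#' stratum boundaries of the IV-free exposure. Pointwise percentile
#' confidence bands come from a bootstrap that resamples individuals
#' within strata (preserving stratum sizes), recomputing every LACE and
#' the curve per draw.
#'
#' @param exposure,outcome,grs,strata As in [lace_per_stratum()].
#' @param laces Optional precomputed [lace_per_stratum()] table.
#' @param n_boot Bootstrap draws (default 500).
#' @param seed Bootstrap seed (required).
#' @param outcome_kind Passed through.
#' @return List of class `piecewise_curve`: `knots`, `values`, `ci_low`,
#'   `ci_high`, `laces`.
#' @export
piecewise_curve <- function(exposure, outcome, grs, strata, laces = NULL,
                            n_boot = 500L, seed = 1L, outcome_kind = NULL) {
  ivfree <- iv_free_exposure(exposure, grs)
  if (is.null(laces))
    laces <- lace_per_stratum(exposure, outcome, grs, strata,
                              ivfree = ivfree, outcome_kind = outcome_kind)
  bad <- laces$flag != ""
  if (sum(!bad) < 2L || any(bad))
    stop("flagged strata break the piecewise chain: ",
         paste(sprintf("stratum %d (%s)", laces$stratum[bad],
                       laces$flag[bad]), collapse = ", "))
  knots <- c(laces$low[1L], laces$high)
  values <- piecewise_values(laces$lace, knots)

  set.seed(as.integer(seed))
  boot_vals <- matrix(NA_real_, nrow = n_boot, ncol = length(knots))
  idx_by_s <- split(seq_along(strata), strata)
  for (b in seq_len(n_boot)) {
    i <- unlist(lapply(idx_by_s, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    lb <- lace_per_stratum(exposure[i], outcome[i], grs[i], strata[i],
                           ivfree = ivfree[i], outcome_kind = outcome_kind)
    if (any(lb$flag != "")) next
    boot_vals[b, ] <- piecewise_values(lb$lace, knots)
  }
  ok <- stats::complete.cases(boot_vals)
  ci <- apply(boot_vals[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975))
  structure(list(knots = knots, values = values,
                 ci_low = ci[1L, ], ci_high = ci[2L, ],
                 laces = laces, n_boot_used = sum(ok)),
            class = "piecewise_curve")
}

#' Heterogeneity and quadratic tests of non-linearity
#'
#' Two tests on the per-stratum LACE estimates: Cochran's Q,
#' `Q = sum((lace_j - lace_IVW)^2 / se_j^2)` against chi-square with
#' S - 1 df, asks whether the LACEs are more heterogeneous than chance;
#' the quadratic test meta-regresses the LACEs on the stratum mean
#' exposures with inverse-variance weights (equivalent to fitting a
#' quadratic exposure-outcome model) and reports the slope, its SE and a
#' normal-theory p-value.
#'
#' @param laces A [lace_per_stratum()] table with >= 3 unflagged strata.
#' @return List with `q_test` (statistic, df, p) and `quadratic_test`
#'   (slope, se, p).
#' @export
nonlinearity_tests <- function(laces) {
  l <- laces[laces$flag == "", , drop = FALSE]
  s <- nrow(l)
  if (s < 3L) stop("need >= 3 unflagged strata")
  w <- 1 / l$se_lace^2
  core <- ivw_core(l$lace, w)
  q_test <- list(statistic = core$Q, df = s - 1L,
                 p = stats::pchisq(core$Q, s - 1L, lower.tail = FALSE))
  # inverse-variance-weighted meta-regression of LACE on stratum mean
  fit <- stats::lm(l$lace ~ l$mean_exposure, weights = w)
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, l$mean_exposure) * sqrt(w))))
  slope <- unname(stats::coef(fit)[2L])
  se <- sqrt(xtx_inv[2L, 2L])
  quadratic_test <- list(slope = slope, se = se,
                         p = 2 * stats::pnorm(-abs(slope / se)))
  list(q_test = q_test, quadratic_test = quadratic_test)
}

#' Stratified non-linear MR in one call
#'
#' Runs the whole non-linear pipeline: IV-free exposure, equal-count
#' strata (deciles by default), per-stratum LACEs, the piecewise-linear
#' causal curve with bootstrap bands, and the two non-linearity tests.
#'
#' @param exposure Exposure vector; its scale (raw kg/m^2-like or SD
#'   units) is the per-unit scale of every LACE, and is echoed in
#'   `exposure_units`.
#' @param outcome Outcome vector.
#' @param grs Instrument vector.
#' @param n_strata Number of strata (default 10, i.e. deciles).
#' @param outcome_kind `"continuous"`, `"binary"` or NULL to infer.
#' @param n_boot,seed Bootstrap settings for the curve bands.
#' @param exposure_units Character tag describing the exposure scale.
#' @param curve If FALSE skip the bootstrap curve (tests only).
#' @return Object of class `lace_profile` with `strata` (LACE table),
#'   `curve`, `tests`, `exposure_units`.
#' @export
mr_nonlinear <- function(exposure, outcome, grs, n_strata = 10L,
                         outcome_kind = NULL, n_boot = 500L, seed = 1L,
                         exposure_units = "exposure units",
                         curve = TRUE) {
  ivfree <- iv_free_exposure(exposure, grs)
  strata <- stratify_exposure(ivfree, n_strata)
  laces <- lace_per_stratum(exposure, outcome, grs, strata,
                            ivfree = ivfree, outcome_kind = outcome_kind)
  tests <- if (sum(laces$flag == "") >= 3L) nonlinearity_tests(laces)
           else NULL
  cv <- if (curve && all(laces$flag == "") && nrow(laces) >= 2L) {
    piecewise_curve(exposure, outcome, grs, strata, laces = laces,
                    n_boot = n_boot, seed = seed,
                    outcome_kind = outcome_kind)
  } else NULL
  structure(list(strata = laces, curve = cv, tests = tests,
                 exposure_units = exposure_units),
            class = "lace_profile")
}

#' @export
print.lace_profile <- function(x, ...) {
  cat(sprintf("Non-linear MR: %d strata of IV-free exposure (per %s)\n",
              nrow(x$strata), x$exposure_units))
  df <- x$strata
  df$lace <- round(df$lace, 4)
  df$se_lace <- round(df$se_lace, 4)
  print.data.frame(df[, c("stratum", "low", "high", "mean_exposure", "n",
                          "lace", "se_lace", "flag")], digits = 4)
  if (!is.null(x$tests)) {
    cat(sprintf("  Cochran's Q = %.2f (df %d), p = %.3g\n",
                x$tests$q_test$statistic, x$tests$q_test$df,
                x$tests$q_test$p))
    cat(sprintf("  quadratic test: slope %.4f (SE %.4f), p = %.3g\n",
                x$tests$quadratic_test$slope, x$tests$quadratic_test$se,
                x$tests$quadratic_test$p))
  }
  invisible(x)
}

#' Plot the piecewise-linear causal curve
#'
#' @param x A `lace_profile` with a fitted curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lace_profile <- function(x, ...) {
  if (is.null(x$curve)) stop("profile has no fitted curve")
  cv <- x$curve
  graphics::plot(cv$knots, cv$values, type = "l", lwd = 2,
                 xlab = paste0("IV-free exposure (", x$exposure_units, ")"),
                 ylab = "causal effect (reference: first knot)", ...)
  graphics::lines(cv$knots, cv$ci_low, lty = 2)
  graphics::lines(cv$knots, cv$ci_high, lty = 2)
  at_mean <- cv$values[-length(cv$values)] +
    x$strata$lace * (x$strata$mean_exposure - cv$knots[-length(cv$knots)])
  graphics::points(x$strata$mean_exposure, at_mean, pch = 16, cex = 0.7)
  invisible(x)
}
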