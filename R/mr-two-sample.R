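#' Per-variant Wald ratio estimates
#'
#' The causal effect identified by a single instrument:
#' `theta_j = beta_outcome_j / beta_exposure_j`, with the first-order delta
#' standard error `se_theta_j = se_outcome_j / |beta_exposure_j|` (the
#' SNP-exposure association treated as known, consistent with the NOME
#' framing of the downstream methods). A second-order option additionally
#' propagates the exposure-side noise.
#'
#' @param h A `harmonized_set` (or any data.frame with `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, optionally `SNP`).
#' @param second_order If TRUE use
#'   `se^2 = se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4`.
#' @return Data.frame of class `ratio_estimates` with columns `SNP`,
#'   `theta`, `se_theta`, `weight` (= 1/se_theta^2); variants with
#'   `beta_exposure == 0` are excluded with reason (attribute `excluded`).
#' @examples
#' wald_ratios(data.frame(beta_exposure = 0.1, se_exposure = 0.01,
#'                        beta_outcome = 0.05, se_outcome = 0.02))
#' @export
wald_ratios <- function(h, second_order = FALSE) {
  bx <- h$beta_exposure
  if (is.null(bx)) stop("input lacks a `beta_exposure` column")
  id <- if (!is.null(h$SNP)) h$SNP else paste0("v", seq_along(bx))
  zero <- !is.na(bx) & bx == 0
  excl <- if (any(zero))
    data.frame(SNP = id[zero], reason = "zero_exposure_beta",
               stringsAsFactors = FALSE)
  else data.frame(SNP = character(), reason = character(),
                  stringsAsFactors = FALSE)
  keep <- !zero & is.finite(bx)
  theta <- h$beta_outcome[keep] / bx[keep]
  se <- if (second_order) {
    sqrt(h$se_outcome[keep]^2 / bx[keep]^2 +
           h$beta_outcome[keep]^2 * h$se_exposure[keep]^2 / bx[keep]^4)
  } else {
    h$se_outcome[keep] / abs(bx[keep])
  }
  out <- data.frame(SNP = id[keep], theta = theta, se_theta = se,
                    weight = 1 / se^2, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  class(out) <- c("ratio_estimates", "data.frame")
  out
}

# inverse-variance-weighted mean + Cochran's Q; shared internal core that
# also serves the k = 1 case (then it reduces to the single Wald ratio)
ivw_core <- function(theta, weight) {
  wsum <- sum(weight)
  est <- sum(weight * theta) / wsum
  q <- sum(weight * (theta - est)^2)
  k <- length(theta)
  se_fixed <- sqrt(1 / wsum)
  scale <- if (k >= 2) max(1, sqrt(q / (k - 1))) else 1
  list(beta = est, se = se_fixed * scale, Q = q, df = k - 1L,
       se_fixed = se_fixed)
}

#' Inverse-variance-weighted (IVW) meta-analysis of Wald ratios
#'
#' Combines the per-variant ratios into a single causal estimate:
#' `theta_hat = sum(w_j theta_j) / sum(w_j)` with `w_j = 1/se_theta_j^2`.
#' Heterogeneity is summarized by Cochran's Q (df = k - 1); the
#' random-effects standard error is multiplicative,
#' `sqrt(1/sum(w)) * max(1, sqrt(Q/(k-1)))`, the usual random-effects
#' convention in summary-statistic MR. CI and p are normal-theory.
#'
#' @param ratios A `ratio_estimates` data.frame from [wald_ratios()].
#' @param scale Scale label carried onto the estimate.
#' @return An [mr_estimate()] with heterogeneity statistics.
#' @examples
#' r <- data.frame(theta = c(1, 3), se_theta = 1, weight = 1)
#' mr_ivw(r)  # estimate 2, Q = 2
#' @export
mr_ivw <- function(ratios, scale = "outcome units per SD exposure") {
  if (nrow(ratios) < 2L)
    stop("IVW needs >= 2 instruments; use the single Wald ratio directly")
  core <- ivw_core(ratios$theta, ratios$weight)
  mr_estimate("IVW", core$beta, core$se, scale = scale,
              n_instruments = nrow(ratios),
              heterogeneity = list(Q = core$Q, df = core$df,
                                   p = stats::pchisq(core$Q, core$df,
                                                     lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome associations on the
#' exposure associations with a free intercept, weights `1/se_outcome^2`,
#' on the exposure-raising orientation. The slope is the causal estimate
#' (consistent under InSIDE even when every variant is pleiotropic); the
#' intercept, with its SE and p-value, is the test for directional
#' pleiotropy. Both standard errors are inflated multiplicatively by
#' `max(1, sqrt(Q_egger/(k-2)))`. P-values are normal by default; a
#' t-reference with k - 2 df is available.
#'
#' @param h A `harmonized_set` (needs `beta_exposure`, `beta_outcome`,
#'   `se_outcome`).
#' @param dist `"normal"` (default) or `"t"` reference for p-values.
#' @param scale Scale label.
#' @return An [mr_estimate()] carrying the intercept test in `$intercept`.
#' @export
mr_egger <- function(h, dist = c("normal", "t"),
                     scale = "outcome units per SD exposure") {
  dist <- match.arg(dist)
  k <- nrow(h)
  if (k < 3L)
    stop("MR-Egger needs >= 3 variants (intercept + slope + residual df)")
  if (any(h$beta_exposure < 0))
    stop("harmonize() first: MR-Egger requires the exposure-raising orientation")
  bx <- h$beta_exposure
  by <- h$beta_outcome
  w <- 1 / h$se_outcome^2
  flags <- character()
  if (stats::sd(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    # degenerate design: intercept and slope are not separable; the fit
    # collapses to the weighted mean of the outcome betas
    wm <- sum(w * by) / sum(w)
    return(mr_estimate("MR-Egger", NA_real_, NA_real_, scale = scale,
                       n_instruments = k, p = NA_real_,
                       intercept = list(value = wm, se = NA_real_,
                                        p = NA_real_),
                       flags = "collinear_design: all exposure betas equal"))
  }
  fit <- stats::lm(by ~ bx, weights = w)
  co <- summary(fit)$coefficients
  res <- by - stats::fitted(fit)
  q <- sum(w * res^2)
  infl <- max(1, sqrt(q / (k - 2)))
  # summary.lm already scales by the weighted residual SD; rebuild the
  # model-based SEs and apply the multiplicative floor explicitly
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
  se0 <- sqrt(diag(xtx_inv))
  se_slope <- se0[2L] * infl
  se_int <- se0[1L] * infl
  pfun <- if (dist == "t") {
    function(est, se) 2 * stats::pt(-abs(est / se), df = k - 2)
  } else {
    function(est, se) 2 * stats::pnorm(-abs(est / se))
  }
  mr_estimate("MR-Egger", co[2L, 1L], se_slope, scale = scale,
              n_instruments = k,
              p = pfun(co[2L, 1L], se_slope),
              heterogeneity = list(Q = q, df = k - 2L,
                                   p = stats::pchisq(q, k - 2,
                                                     lower.tail = FALSE)),
              intercept = list(value = co[1L, 1L], se = se_int,
                               p = pfun(co[1L, 1L], se_int)),
              flags = flags)
}

# weighted-median point estimate: sort, normalize weights, interpolate the
# cumulative weight midpoints at 0.5
weighted_median_estimate <- function(theta, weight) {
  o <- order(theta)
  th <- theta[o]
  p <- weight[o] / sum(weight)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1L]) return(th[1L])
  if (0.5 >= s[length(s)]) return(th[length(s)])
  stats::approx(s, th, xout = 0.5, ties = "ordered")$y
}

penalize_weights <- function(theta, weight, penalty = 20) {
  est <- weighted_median_estimate(theta, weight)
  q_j <- weight * (theta - est)^2
  p_j <- stats::pchisq(q_j, df = 1, lower.tail = FALSE)
  weight * pmin(1, penalty * p_j)
}

#' Weighted median and penalized weighted median estimators
#'
#' The weighted median is consistent when at least half of the analysis
#' weight comes from valid instruments: order the Wald ratios, form
#' cumulative normalized-weight midpoints, and interpolate at 50\%. The
#' penalized variant first downweights heterogeneous variants by their
#' Cochran's Q contribution: `q_j = w_j (theta_j - theta_WM)^2`,
#' `w'_j = w_j * min(1, penalty * P(chi2_1 > q_j))` with penalty constant
#' 20, then re-runs the weighted median. Standard errors come from a
#' parametric bootstrap: each SNP's exposure and outcome betas are
#' resampled from normal(observed, SE) and the estimator recomputed.
#'
#' @param h A `harmonized_set` (beta/SE columns required; the bootstrap
#'   resamples at the beta level).
#' @param n_boot Bootstrap draws (default 1000; < 100 draws a warning).
#' @param seed Seed for the bootstrap (required for reproducibility).
#' @param penalty Penalty constant for the penalized variant.
#' @param scale Scale label.
#' @return An [mr_estimate()].
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = 1L,
                               scale = "outcome units per SD exposure") {
  median_mr(h, n_boot, seed, penalized = FALSE, scale = scale)
}

#' @rdname mr_weighted_median
#' @export
mr_penalized_weighted_median <- function(h, n_boot = 1000L, seed = 1L,
                                         penalty = 20,
                                         scale = "outcome units per SD exposure") {
  median_mr(h, n_boot, seed, penalized = TRUE, penalty = penalty,
            scale = scale)
}

median_mr <- function(h, n_boot, seed, penalized, penalty = 20, scale) {
  r <- wald_ratios(h)
  if (nrow(r) < 2L) stop("median estimators need >= 2 instruments")
  if (n_boot < 100L)
    warning("n_boot < 100: bootstrap SE will be unstable")
  point <- function(theta, weight) {
    w <- if (penalized) penalize_weights(theta, weight, penalty) else weight
    weighted_median_estimate(theta, w)
  }
  est <- point(r$theta, r$weight)
  set.seed(as.integer(seed))
  k <- nrow(h)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
    by <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
    ok <- bx != 0
    th <- by[ok] / bx[ok]
    se <- h$se_outcome[ok] / abs(bx[ok])
    boot[b] <- point(th, 1 / se^2)
  }
  se_b <- stats::sd(boot)
  mr_estimate(if (penalized) "Penalized weighted median"
              else "Weighted median",
              est, se_b, scale = scale, n_instruments = nrow(r))
}

#' Run every two-sample MR method on one harmonized set
#'
#' Convenience wrapper producing IVW, MR-Egger, weighted median and
#' penalized weighted median estimates (Egger is skipped with fewer than 3
#' variants).
#'
#' @param h A `harmonized_set`.
#' @param n_boot,seed Bootstrap settings for the median estimators.
#' @param scale Scale label.
#' @return Named list of [mr_estimate()] objects.
#' @export
mr_two_sample_all <- function(h, n_boot = 1000L, seed = 1L,
                              scale = "outcome units per SD exposure") {
  r <- wald_ratios(h)
  out <- list(ivw = mr_ivw(r, scale = scale))
  if (nrow(h) >= 3L) out$egger <- mr_egger(h, scale = scale)
  out$weighted_median <- mr_weighted_median(h, n_boot, seed, scale = scale)
  out$penalized_weighted_median <-
    mr_penalized_weighted_median(h, n_boot, seed, scale = scale)
  out
}
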