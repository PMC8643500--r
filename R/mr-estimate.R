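#' Construct an MR causal-effect estimate
#'
#' Container shared by every estimator in the package: a point estimate
#' with its scale, normal-theory (or bootstrap) standard error, 95\% CI,
#' p-value, instrument count, and method-specific extras (Cochran's Q
#' heterogeneity, Egger intercept, weak-instrument flag).
#'
#' @param method Method label (e.g. `"IVW"`, `"MR-Egger"`).
#' @param beta Point estimate.
#' @param se Standard error.
#' @param scale Character scale description (e.g.
#'   `"log-odds per SD exposure"`).
#' @param n_instruments Number of instruments combined.
#' @param p Optional p-value; by default `2 * pnorm(-|beta/se|)`.
#' @param heterogeneity Optional list `(Q, df, p)`.
#' @param intercept Optional list `(value, se, p)` (MR-Egger).
#' @param n,n_cases,n_controls Optional sample sizes.
#' @param flags Character vector of warnings attached to the estimate.
#' @return Object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, scale = "outcome units per SD exposure",
                        n_instruments = NA_integer_, p = NULL,
                        heterogeneity = NULL, intercept = NULL,
                        n = NA_integer_, n_cases = NA_integer_,
                        n_controls = NA_integer_, flags = character()) {
  z <- stats::qnorm(0.975)
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - z * se, ci_high = beta + z * se,
                 p = p, scale = scale,
                 n_instruments = n_instruments,
                 heterogeneity = heterogeneity, intercept = intercept,
                 n = n, n_cases = n_cases, n_controls = n_controls,
                 flags = flags),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%s)\n", x$method, x$scale))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$p))
  if (grepl("log-odds", x$scale))
    cat(sprintf("  OR = %.3f (95%% CI %.3f, %.3f)\n",
                exp(x$beta), exp(x$ci_low), exp(x$ci_high)))
  if (!is.na(x$n_instruments))
    cat(sprintf("  instruments: %d\n", x$n_instruments))
  if (!is.null(x$heterogeneity))
    cat(sprintf("  Cochran's Q = %.2f (df %d), p = %.3g\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$p))
  if (!is.null(x$intercept))
    cat(sprintf("  Egger intercept = %.4f (SE %.4f), p = %.3g\n",
                x$intercept$value, x$intercept$se, x$intercept$p))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.mr_estimate <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$beta, object$method)
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              nrow = 1,
              dimnames = list(object$method,
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, scale = x$scale, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             n_instruments = x$n_instruments,
             q_statistic = if (!is.null(x$heterogeneity))
               x$heterogeneity$Q else NA_real_,
             q_p = if (!is.null(x$heterogeneity))
               x$heterogeneity$p else NA_real_,
             egger_intercept = if (!is.null(x$intercept))
               x$intercept$value else NA_real_,
             egger_intercept_p = if (!is.null(x$intercept))
               x$intercept$p else NA_real_,
             flags = if (length(x$flags)) paste(x$flags, collapse = ";")
                     else "", stringsAsFactors = FALSE)
}
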