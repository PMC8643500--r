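#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles through their ranks using the Blom
#' offset: `z_i = qnorm((r_i - 3/8) / (n + 1/4))`. The output has mean
#' approximately 0 and SD approximately 1, preserves rank order, and is
#' invariant to any strictly monotone transform of the input. Ties receive
#' the average rank, so tied inputs map to the same z-score. Adiposity
#' measures (BMI, body fat percentage) are transformed this way before any
#' regression so effects are per 1 SD of exposure.
#'
#' @param x Numeric vector with at least 2 distinct finite values; NAs are
#'   propagated.
#' @return Numeric vector of z-scores, same length as `x`.
#' @examples
#' inverse_normal_transform(c(10, 20, 30, 40, 50))
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 2L || !all(is.finite(v)))
    stop("need at least 2 finite values")
  if (length(unique(v)) < 2L)
    stop("all values identical: ranks (and the transform) are undefined")
  n <- length(v)
  r <- rank(v, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  out
}

#' Covariate-adjusted observational exposure-outcome association
#'
#' Fits the observational (non-genetic) regression of a mental-health
#' outcome on the standardized exposure: logistic regression for binary
#' outcomes (effect reported as an odds ratio per 1-SD exposure) and linear
#' regression for continuous scores (slope per 1-SD exposure). The default
#' adjustment set is age, sex, assessment centre, deprivation index and
#' smoking status; sex-stratified fits drop sex from the adjustment set.
#' Additional adjustment variables (e.g. another outcome, for mutual
#' depression/anxiety adjustment) can be named in `covariates`.
#'
#' @param cohort A `cohort` object (or a data.frame holding outcome,
#'   exposure and covariate columns).
#' @param outcome Outcome column name.
#' @param exposure Exposure vector name: `"exposure"` (standardized) or a
#'   column of the covariate table.
#' @param covariates Character vector of adjustment column names (from the
#'   cohort covariate table or outcome table).
#' @param stratum `"all"`, `"male"` or `"female"` (sex coded 1 = male).
#' @return An object of class `obs_estimate`: effect (OR or slope), CI,
#'   p-value, counts, adjustment set, and a `status` field (`"ok"`,
#'   `"separation"`, `"nonconvergence"`) — the estimate is withheld (NA)
#'   unless status is `"ok"`.
#' @export
fit_observational <- function(cohort, outcome,
                              exposure = "exposure",
                              covariates = c("age", "sex", "centre",
                                             "deprivation", "smoking"),
                              stratum = c("all", "male", "female")) {
  stratum <- match.arg(stratum)
  df <- observational_frame(cohort, outcome, exposure, covariates)
  if (stratum != "all") {
    keep <- df$.sexcol == (if (stratum == "male") 1 else 0)
    df <- df[keep, , drop = FALSE]
    covariates <- setdiff(covariates, "sex")
  }
  model_cols <- c(".outcome", ".exposure", covariates)
  df <- df[stats::complete.cases(df[, model_cols, drop = FALSE]), ,
           drop = FALSE]
  y <- df$.outcome
  binary <- all(y %in% c(0, 1)) && length(unique(y)) == 2L

  rhs <- paste(c(".exposure", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".outcome ~", rhs))
  status <- "ok"
  if (binary) {
    fit <- withCallingHandlers(
      stats::glm(fml, data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8,
                                              maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          status <<- "separation"
        invokeRestart("muffleWarning")
      })
    if (!fit$converged) status <- "nonconvergence"
  } else {
    fit <- stats::lm(fml, data = df)
  }
  co <- summary(fit)$coefficients
  b <- co[".exposure", 1L]
  se <- co[".exposure", 2L]
  z <- stats::qnorm(0.975)
  est <- if (status == "ok") {
    if (binary) list(effect = exp(b), ci_low = exp(b - z * se),
                     ci_high = exp(b + z * se))
    else list(effect = b, ci_low = b - z * se, ci_high = b + z * se)
  } else list(effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_)

  structure(list(
    outcome = outcome, exposure = exposure, stratum = stratum,
    scale = if (binary) "odds ratio per SD exposure"
            else "outcome units per SD exposure",
    effect = est$effect, ci_low = est$ci_low, ci_high = est$ci_high,
    p = if (status == "ok") co[".exposure", 4L] else NA_real_,
    n_total = nrow(df),
    n_cases = if (binary) sum(y == 1) else NA_integer_,
    n_controls = if (binary) sum(y == 0) else NA_integer_,
    adjustment = covariates, status = status,
    beta = b, se = se
  ), class = "obs_estimate")
}

# assemble the modelling frame from a cohort (or plain data.frame)
observational_frame <- function(cohort, outcome, exposure, covariates) {
  if (inherits(cohort, "cohort")) {
    pool <- cbind(cohort$covariates, cohort$outcomes)
    pool$exposure <- cohort$exposure
    pool$exposure_raw <- cohort$exposure_raw
  } else {
    pool <- as.data.frame(cohort)
  }
  missing_cols <- setdiff(c(outcome, exposure, covariates), names(pool))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  df <- pool[, unique(c(outcome, exposure, covariates)), drop = FALSE]
  df$.outcome <- pool[[outcome]]
  df$.exposure <- pool[[exposure]]
  df$.sexcol <- if ("sex" %in% names(pool)) pool$sex else NA_integer_
  df
}

#' @export
print.obs_estimate <- function(x, ...) {
  cat(sprintf("Observational association: %s ~ %s (%s)\n",
              x$outcome, x$exposure, x$stratum))
  if (x$status != "ok") {
    cat(sprintf("  estimate withheld: %s\n", x$status))
  } else {
    cat(sprintf("  %s: %.3f (95%% CI %.3f, %.3f), p = %.3g\n",
                x$scale, x$effect, x$ci_low, x$ci_high, x$p))
  }
  cat(sprintf("  n = %d%s; adjusted for: %s\n", x$n_total,
              if (!is.na(x$n_cases))
                sprintf(" (%d cases / %d controls)", x$n_cases, x$n_controls)
              else "",
              if (length(x$adjustment)) paste(x$adjustment, collapse = ", ")
              else "nothing"))
  invisible(x)
}

#' @export
as.data.frame.obs_estimate <- function(x, ...) {
  data.frame(method = "observational", outcome = x$outcome,
             stratum = x$stratum, scale = x$scale, effect = x$effect,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             n = x$n_total, status = x$status, stringsAsFactors = FALSE)
}
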