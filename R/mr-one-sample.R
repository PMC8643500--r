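#' Two-stage least-squares MR on individual-level data
#'
#' Stage 1 regresses the (standardized) exposure on the genetic risk score
#' plus any covariates; stage 2 regresses the outcome on the stage-1 fitted
#' values plus the same covariates — linear for continuous outcomes,
#' logistic for binary ones (the estimate is then on the log-odds scale,
#' reported alongside the OR). For the linear-linear case the standard
#' error is the proper 2SLS one, recomputed from the structural residuals
#' `y - X beta_hat` (observed exposure, not fitted values). For the
#' logistic second stage the model SE is reported as-is — a known
#' limitation (the fitted-value plug-in understates uncertainty and the OR
#' is non-collapsible) — with an optional individual-resampling bootstrap
#' SE. A first-stage F below 10 attaches a weak-instrument flag.
#'
#' @param cohort A `cohort` object, or a list/data.frame carrying the
#'   needed columns.
#' @param outcome Outcome column name (in `cohort$outcomes`).
#' @param grs Instrument vector; defaults to [cohort_grs()] with truth
#'   weights.
#' @param covariates Character vector of covariate names to include in both
#'   stages (default none).
#' @param outcome_kind `"continuous"`, `"binary"`, or NULL to infer from
#'   the outcome values.
#' @param se_method `"analytic"` (default) or `"bootstrap"` (resamples
#'   individuals and redoes both stages).
#' @param n_boot,seed Bootstrap settings when `se_method = "bootstrap"`.
#' @param subset Optional logical vector restricting the analysis rows.
#' @return An [mr_estimate()]; `$first_stage` holds the instrument-strength
#'   diagnostics.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 1000, seed = 5))
#' tsls(coh, "y")
#' @export
tsls <- function(cohort, outcome = "y", grs = NULL,
                 covariates = character(), outcome_kind = NULL,
                 se_method = c("analytic", "bootstrap"),
                 n_boot = 1000L, seed = 1L, subset = NULL) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(grs)) grs <- cohort_grs(cohort)
  y <- cohort$outcomes[[outcome]]
  if (is.null(y)) stop("outcome not found: ", outcome)
  x <- cohort$exposure
  cv <- if (length(covariates))
    cohort$covariates[, covariates, drop = FALSE] else NULL

  if (!is.null(subset)) {
    stopifnot(is.logical(subset), length(subset) == length(y))
    y <- y[subset]; x <- x[subset]; grs <- grs[subset]
    if (!is.null(cv)) cv <- cv[subset, , drop = FALSE]
  }
  ok <- !is.na(y)  # derived subtype outcomes code the other cases NA
  if (!all(ok)) {
    y <- y[ok]; x <- x[ok]; grs <- grs[ok]
    if (!is.null(cv)) cv <- cv[ok, , drop = FALSE]
  }
  if (length(y) == 0L) stop("empty analysis set")
  if (is.null(outcome_kind)) {
    outcome_kind <- if (all(y %in% c(0, 1)) && length(unique(y)) == 2L)
      "binary" else "continuous"
  }
  est <- tsls_fit(x, y, grs, cv, outcome_kind)

  if (se_method == "bootstrap") {
    set.seed(as.integer(seed))
    n <- length(y)
    bs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      bs[b] <- tsls_fit(x[i], y[i], grs[i],
                        if (!is.null(cv)) cv[i, , drop = FALSE] else NULL,
                        outcome_kind, point_only = TRUE)
    }
    est$se <- stats::sd(bs)
  }

  strength <- instrument_strength(grs, x)
  flags <- character()
  if (strength$weak_flag) flags <- c(flags, "weak_instrument: F < 10")
  out <- mr_estimate(
    method = "2SLS",
    beta = est$beta, se = est$se,
    scale = if (outcome_kind == "binary") "log-odds per SD exposure"
            else "SD outcome per SD exposure",
    n_instruments = attr(grs, "n_variants") %||% 1L,
    n = length(y),
    n_cases = if (outcome_kind == "binary") sum(y == 1) else NA_integer_,
    n_controls = if (outcome_kind == "binary") sum(y == 0) else NA_integer_,
    flags = flags)
  out$first_stage <- strength
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# core 2SLS fit; covariates enter both stages
tsls_fit <- function(x, y, grs, cv, outcome_kind, point_only = FALSE) {
  cmat <- if (!is.null(cv) && ncol(cv))
    stats::model.matrix(~ ., data = cv)[, -1L, drop = FALSE] else NULL
  z1 <- cbind(1, grs, cmat)
  qz <- qr(z1)
  xhat <- qr.fitted(qz, x)

  if (outcome_kind == "continuous") {
    x2 <- cbind(1, xhat, cmat)
    fit <- stats::lm.fit(x2, y)
    beta <- fit$coefficients[2L]
    if (point_only) return(beta)
    # proper 2SLS residuals use the observed exposure
    xobs <- cbind(1, x, cmat)
    resid <- y - drop(xobs %*% fit$coefficients)
    n <- length(y)
    p <- ncol(x2)
    sigma2 <- sum(resid^2) / (n - p)
    xtx_inv <- chol2inv(qr.R(qr(x2)))
    se <- sqrt(sigma2 * xtx_inv[2L, 2L])
    list(beta = unname(beta), se = se)
  } else {
    fit <- stats::glm.fit(cbind(1, xhat, cmat), y,
                          family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-8,
                                                       maxit = 100))
    if (!fit$converged) stop("stage-2 logistic regression did not converge")
    beta <- fit$coefficients[2L]
    if (point_only) return(beta)
    xw <- cbind(1, xhat, cmat) * sqrt(fit$weights)
    se <- sqrt(chol2inv(chol(crossprod(xw)))[2L, 2L])
    list(beta = unname(beta), se = se)
  }
}

#' Re-run an analysis on a subset defined by an exclusion rule
#'
#' Sensitivity analysis of the "exclude individuals on antidepressants"
#' type: a declarative predicate over the cohort's covariate and outcome
#' columns selects individuals to drop, and the identical estimator is
#' re-run on the retained subset. Retained/excluded counts are attached to
#' the estimate.
#'
#' @param cohort A `cohort` object.
#' @param exclude Either a logical vector (TRUE = exclude) or a one-sided
#'   formula evaluated in the cohort's covariate+outcome frame, e.g.
#'   `~ on_medication == 1`.
#' @param ... Passed to [tsls()].
#' @return An [mr_estimate()] with `$exclusion` = list(retained, excluded).
#' @export
run_exclusion_sensitivity <- function(cohort, exclude, ...) {
  stopifnot(inherits(cohort, "cohort"))
  frame <- cbind(cohort$covariates, cohort$outcomes)
  frame$exposure <- cohort$exposure
  if (inherits(exclude, "formula")) {
    sel <- eval(exclude[[2L]], envir = frame)
  } else {
    sel <- exclude
  }
  if (!is.logical(sel) || length(sel) != nrow(frame))
    stop("exclusion rule must yield one logical per individual")
  keep <- !sel & !is.na(sel)
  if (!any(keep)) stop("exclusion rule removed every individual")
  est <- tsls(cohort, subset = keep, ...)
  est$exclusion <- list(retained = sum(keep), excluded = sum(!keep))
  est
}

#' Split a binary outcome's cases into a subtype and the remainder
#'
#' Derives two new binary outcomes from an existing case/control outcome:
#' `<outcome>_subtype` (subtype cases vs controls; the remaining cases set
#' to NA so they drop out of that analysis) and `<outcome>_other`
#' (remaining cases vs controls). Mirrors sensitivity analyses of the
#' "atypical depression" type, where cases defined by weight gain are
#' analysed apart from the rest.
#'
#' @param cohort A `cohort` object.
#' @param outcome Binary outcome column name.
#' @param case_rule Logical vector (length n) or one-sided formula selecting
#'   the subtype *among cases*; non-case rows are ignored.
#' @return The cohort with the two derived outcomes appended.
#' @export
recode_case_subtype <- function(cohort, outcome, case_rule) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$outcomes[[outcome]]
  if (is.null(y)) stop("outcome not found: ", outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  frame <- cbind(cohort$covariates, cohort$outcomes)
  frame$exposure <- cohort$exposure
  sel <- if (inherits(case_rule, "formula"))
    eval(case_rule[[2L]], envir = frame) else case_rule
  sel <- sel & y == 1
  if (!any(sel)) stop("case rule selected zero cases")
  sub <- ifelse(y == 0, 0L, ifelse(sel, 1L, NA_integer_))
  oth <- ifelse(y == 0, 0L, ifelse(!sel, 1L, NA_integer_))
  cohort$outcomes[[paste0(outcome, "_subtype")]] <- sub
  cohort$outcomes[[paste0(outcome, "_other")]] <- oth
  cohort
}
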