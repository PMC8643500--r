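#' Derive two-sample GWAS summary statistics from a cohort
#'
#' Splits the cohort into two disjoint subsets and computes per-SNP
#' exposure associations (simple linear regression) in the first subset and
#' per-SNP outcome associations (linear for continuous outcomes, logistic
#' for binary) in the second. Using disjoint subsets makes the resulting
#' exposure/outcome statistics independent, the defining feature of a
#' two-sample MR design drawn from one population.
#'
#' @param cohort A `cohort` object.
#' @param outcome_name Name of the outcome column to scan.
#' @param split Fraction of individuals assigned to the exposure subset,
#'   in (0, 1).
#' @param seed Seed for the random split (defaults to the cohort seed + 4).
#' @return A data.frame of class `summary_stats` with columns `SNP`, `EA`,
#'   `OA`, `EAF`, `beta_exposure`, `se_exposure`, `p_exposure`,
#'   `n_exposure`, `beta_outcome`, `se_outcome`, `p_outcome`, `n_outcome`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 2000, seed = 3))
#' head(cohort_to_summary_stats(coh, "y"))
#' @export
cohort_to_summary_stats <- function(cohort, outcome_name = "y", split = 0.5,
                                    seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (!is.numeric(split) || length(split) != 1L || split <= 0 || split >= 1)
    stop("`split` must lie strictly inside (0, 1)")
  if (!outcome_name %in% names(cohort$outcomes))
    stop("outcome not found in cohort: ", outcome_name)
  if (is.null(seed)) seed <- seed_offset(cohort$truth$config$seed, 4L)
  set.seed(seed)

  n <- nrow(cohort$genotypes)
  idx1 <- sort(sample.int(n, size = floor(split * n)))
  idx2 <- setdiff(seq_len(n), idx1)
  y <- cohort$outcomes[[outcome_name]]
  binary <- all(y %in% c(0, 1)) && length(unique(y)) == 2L

  exp_scan <- linear_scan(cohort$genotypes[idx1, , drop = FALSE],
                          cohort$exposure[idx1])
  Gout <- cohort$genotypes[idx2, , drop = FALSE]
  out_scan <- if (binary) logistic_scan(Gout, y[idx2])
              else linear_scan(Gout, y[idx2])

  res <- data.frame(
    SNP = colnames(cohort$genotypes),
    EA = cohort$truth$ea,
    OA = cohort$truth$oa,
    EAF = colMeans(cohort$genotypes) / 2,
    beta_exposure = exp_scan$beta,
    se_exposure = exp_scan$se,
    p_exposure = exp_scan$p,
    n_exposure = length(idx1),
    beta_outcome = out_scan$beta,
    se_outcome = out_scan$se,
    p_outcome = out_scan$p,
    n_outcome = length(idx2),
    stringsAsFactors = FALSE
  )
  class(res) <- c("summary_stats", "data.frame")
  res
}

#' Simulate instrument-level summary statistics directly
#'
#' Generates per-SNP exposure and outcome association estimates straight at
#' the summary level, for studies of the two-sample estimators themselves
#' (calibration of the Egger intercept test, robustness of the median
#' estimators) where individual-level simulation adds nothing. True
#' SNP-exposure effects `gamma_j` are drawn uniformly positive (the
#' harmonized, exposure-raising orientation); estimates are
#' `gamma_j + N(0, se_exposure^2)` and
#' `theta * gamma_j + alpha_j + N(0, se_outcome^2)`, with the direct
#' effects `alpha_j` controlled exactly as in [simulate_outcome()].
#'
#' @param n_snps Number of instruments.
#' @param theta True causal effect.
#' @param gamma_range Range of true SNP-exposure effects (uniform draw).
#' @param se_exposure,se_outcome Per-SNP standard errors (recycled).
#' @param pleiotropy_mode,pleiotropy_sd,pleiotropy_mean,inside_rho As in
#'   [sim_config()].
#' @param n_invalid For partial contamination: only the first `n_invalid`
#'   SNPs receive nonzero `alpha_j` (default: all, per `pleiotropy_mode`).
#' @param seed Integer seed.
#' @return A data.frame usable by [wald_ratios()], [mr_egger()] and the
#'   median estimators, with columns `SNP`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome` and attributes `gamma`, `alpha`, `theta`.
#' @export
simulate_summary_stats <- function(n_snps = 72L, theta = 0.1,
                                   gamma_range = c(0.05, 0.15),
                                   se_exposure = 0.001, se_outcome = 0.05,
                                   pleiotropy_mode = c("none", "balanced",
                                                       "directional",
                                                       "inside_violating"),
                                   pleiotropy_sd = 0, pleiotropy_mean = 0,
                                   inside_rho = 0.5,
                                   n_invalid = NULL, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  set.seed(as.integer(seed))
  m <- as.integer(n_snps)
  gamma <- stats::runif(m, gamma_range[1], gamma_range[2])
  alpha <- switch(pleiotropy_mode,
    none = rep(0, m),
    balanced = stats::rnorm(m, 0, pleiotropy_sd),
    directional = stats::rnorm(m, pleiotropy_mean, pleiotropy_sd),
    inside_violating = inside_rho * gamma + stats::rnorm(m, 0, pleiotropy_sd))
  if (!is.null(n_invalid)) {
    stopifnot(n_invalid >= 0, n_invalid <= m)
    if (n_invalid < m) alpha[(n_invalid + 1L):m] <- 0
  }
  se_g <- rep_len(se_exposure, m)
  se_o <- rep_len(se_outcome, m)
  res <- data.frame(
    SNP = paste0("rs", seq_len(m)),
    beta_exposure = gamma + stats::rnorm(m, 0, se_g),
    se_exposure = se_g,
    beta_outcome = theta * gamma + alpha + stats::rnorm(m, 0, se_o),
    se_outcome = se_o,
    stringsAsFactors = FALSE
  )
  attr(res, "gamma") <- gamma
  attr(res, "alpha") <- alpha
  attr(res, "theta") <- theta
  res
}
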