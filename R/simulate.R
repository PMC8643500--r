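#' Simulate unlinked biallelic genotype dosages
#'
#' Draws an n x M dosage matrix under Hardy-Weinberg equilibrium: per SNP a
#' minor-allele frequency is drawn uniformly from `config$maf_range` and
#' dosages are binomial(2, MAF). SNPs are simulated independent (no LD),
#' matching the use of pre-pruned genome-wide-significant loci as
#' instruments. Effect/other alleles are assigned per SNP so the matrix can
#' round-trip through summary-statistic formats.
#'
#' @param config A [sim_config()] object.
#' @return Integer matrix of dosages in \{0, 1, 2\} with column names
#'   `rs1..rsM` and attributes `maf`, `ea`, `oa` (per-SNP allele labels).
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 100, n_snps = 5))
#' colMeans(g) / 2  # close to attr(g, "maf")
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed_offset(config$seed, 0L))
  n <- config$n_individuals
  m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pair <- matrix(replicate(m, sample(c("A", "C", "G", "T"), 2L)), nrow = 2L)
  g <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  colnames(g) <- paste0("rs", seq_len(m))
  attr(g, "maf") <- maf
  attr(g, "ea") <- pair[1L, ]
  attr(g, "oa") <- pair[2L, ]
  g
}

#' Simulate a standardized exposure from genotypes
#'
#' The exposure is built as `sum_j gamma_j g_ij + a U_i + e_i` with U a
#' standard-normal confounder and per-allele effects gamma_j scaled so the
#' genetic score explains `exposure_h2` of the exposure variance (using the
#' Hardy-Weinberg variance 2 MAF (1-MAF) per SNP). The result is
#' standardized to mean 0, SD 1; a raw BMI-like scale is attached via
#' `exposure_mean_raw + exposure_sd_raw * x`.
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param config The same [sim_config()] object.
#' @return List with `exposure` (standardized), `exposure_raw`, `confounder`,
#'   and the realized per-allele effects `gamma`.
#' @export
simulate_exposure <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$exposure_h2 >= 1) stop("`exposure_h2` must be < 1")
  set.seed(seed_offset(config$seed, 1L))
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  maf <- attr(genotypes, "maf")
  if (is.null(maf)) maf <- colMeans(genotypes) / 2
  a <- config$confounder_effect_exposure
  u <- stats::rnorm(n)

  if (config$exposure_h2 == 0) {
    gamma <- rep(0, m)
  } else {
    gamma_raw <- stats::rnorm(m)
    var_g <- 2 * maf * (1 - maf)
    v0 <- sum(gamma_raw^2 * var_g)
    gamma <- gamma_raw * sqrt(config$exposure_h2 / v0)
  }
  score <- drop(genotypes %*% gamma)
  e_sd <- sqrt(1 - config$exposure_h2 - a^2)
  x <- score + a * u + stats::rnorm(n, sd = e_sd)
  x <- (x - mean(x)) / stats::sd(x)
  list(exposure = x,
       exposure_raw = config$exposure_mean_raw + config$exposure_sd_raw * x,
       confounder = u,
       gamma = gamma)
}

# causal function f(x) on the standardized exposure scale; `sex` (0/1)
# optionally shifts the linear slope by config$sex_effect
causal_fn <- function(x, config, sex = NULL) {
  theta <- config$causal_coef
  if (!is.null(sex) && config$sex_effect != 0 &&
      config$causal_function == "linear") {
    return((theta + config$sex_effect * sex) * x)
  }
  switch(config$causal_function,
         linear = theta * x,
         quadratic = theta * x^2,
         threshold = theta * pmax(x - config$threshold, 0),
         stop("unknown causal_function: ", config$causal_function))
}

# solve the logistic liability intercept so that mean p equals the target
# prevalence; bisection on the mean predicted probability, tolerance 1e-4
solve_liability_intercept <- function(eta, prevalence, tol = 1e-4) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence not bracketed by intercept")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol * min(prevalence, 1 - prevalence)) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Simulate an outcome with configurable causal shape and pleiotropy
#'
#' Builds the latent scale `eta_i = f(x_i) + b U_i + sum_j alpha_j g_ij +
#' e_i` and returns either `eta` itself (continuous outcomes, unit residual
#' SD) or a Bernoulli draw through `logistic(c0 + eta)` with the intercept
#' `c0` solved so the mean prevalence matches `config$binary_prevalence`.
#' Direct (pleiotropic) SNP effects `alpha_j` follow `pleiotropy_mode`:
#' `"none"` (all zero), `"balanced"` (mean zero), `"directional"` (nonzero
#' mean, independent of gamma_j so InSIDE holds), or `"inside_violating"`
#' (`alpha_j = inside_rho * gamma_j + noise`).
#'
#' @param exposure Standardized exposure vector.
#' @param genotypes Dosage matrix.
#' @param confounder Confounder vector U.
#' @param config The [sim_config()] object.
#' @param sex Optional 0/1 vector enabling a sex-specific causal slope.
#' @param gamma Realized SNP-exposure effects (needed for
#'   `"inside_violating"`); defaults to zeros.
#' @return List with `outcome`, the realized `alpha`, and the liability
#'   intercept `c0` (NA for continuous outcomes).
#' @export
simulate_outcome <- function(exposure, genotypes, confounder, config,
                             sex = NULL, gamma = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed_offset(config$seed, 2L))
  n <- length(exposure)
  m <- ncol(genotypes)
  if (is.null(gamma)) gamma <- rep(0, m)

  alpha <- switch(config$pleiotropy_mode,
    none = rep(0, m),
    balanced = stats::rnorm(m, 0, config$pleiotropy_sd),
    directional = stats::rnorm(m, config$pleiotropy_mean,
                               config$pleiotropy_sd),
    inside_violating = config$inside_rho * gamma +
      stats::rnorm(m, 0, config$pleiotropy_sd))

  eta <- causal_fn(exposure, config, sex) +
    config$confounder_effect_outcome * confounder +
    drop(genotypes %*% alpha) +
    stats::rnorm(n)

  if (config$outcome_kind == "continuous") {
    list(outcome = eta, alpha = alpha, c0 = NA_real_)
  } else {
    c0 <- solve_liability_intercept(eta, config$binary_prevalence)
    y <- stats::rbinom(n, 1L, stats::plogis(c0 + eta))
    list(outcome = y, alpha = alpha, c0 = c0)
  }
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_genotypes()], [simulate_exposure()] and
#' [simulate_outcome()] under one configuration and adds baseline
#' covariates (age in years, sex 0/1, assessment centre, a deprivation
#' index, smoking status) drawn independently of genotype. The generating
#' truth (config, realized gamma/alpha, MAFs, allele labels, liability
#' intercept) is kept on the object so downstream estimators can be checked
#' by parameter recovery.
#'
#' @param config A [sim_config()] object.
#' @param outcome_name Column name for the simulated outcome.
#' @return An object of class `cohort`: list with `genotypes`, `exposure`
#'   (standardized), `exposure_raw`, `covariates` (data.frame), `outcomes`
#'   (data.frame), `confounder` and `truth`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 500, seed = 7))
#' coh
#' @export
simulate_cohort <- function(config, outcome_name = "y") {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genotypes(config)
  ex <- simulate_exposure(g, config)

  set.seed(seed_offset(config$seed, 3L))
  n <- config$n_individuals
  covariates <- data.frame(
    age = round(stats::runif(n, 40, 70)),
    sex = stats::rbinom(n, 1L, 0.5),
    centre = factor(sample(paste0("c", 1:10), n, replace = TRUE)),
    deprivation = stats::rnorm(n, -1.8, 2.8),
    smoking = factor(sample(c("never", "former", "current"), n,
                            replace = TRUE, prob = c(0.58, 0.36, 0.06)))
  )

  out <- simulate_outcome(ex$exposure, g, ex$confounder, config,
                          sex = covariates$sex, gamma = ex$gamma)
  outcomes <- stats::setNames(data.frame(out$outcome), outcome_name)

  structure(list(
    genotypes = g,
    exposure = ex$exposure,
    exposure_raw = ex$exposure_raw,
    covariates = covariates,
    outcomes = outcomes,
    confounder = ex$confounder,
    truth = list(config = config, gamma = ex$gamma, alpha = out$alpha,
                 maf = attr(g, "maf"), ea = attr(g, "ea"),
                 oa = attr(g, "oa"), c0 = out$c0)
  ), class = "cohort")
}

#' Add a further simulated outcome to an existing cohort
#'
#' Re-uses the cohort's genotypes, exposure and confounder but draws a new
#' outcome under modified settings (causal shape, outcome kind, prevalence,
#' pleiotropy). The new outcome's randomness is driven by `seed`, so a
#' cohort can host several reproducible outcomes.
#'
#' @param cohort A `cohort` object.
#' @param outcome_name Name of the new outcome column.
#' @param seed Seed for the new outcome's draw.
#' @param ... `sim_config()` fields to override (e.g. `causal_coef`,
#'   `outcome_kind`, `binary_prevalence`, `pleiotropy_mode`).
#' @return The cohort with the outcome appended and its truth recorded in
#'   `truth$outcomes[[outcome_name]]`.
#' @export
add_outcome <- function(cohort, outcome_name, seed, ...) {
  stopifnot(inherits(cohort, "cohort"))
  cfg0 <- cohort$truth$config
  over <- list(...)
  cfg <- utils::modifyList(unclass(cfg0), over)
  cfg$seed <- as.integer(seed) - 2L  # simulate_outcome offsets by +2
  class(cfg) <- "sim_config"
  out <- simulate_outcome(cohort$exposure, cohort$genotypes,
                          cohort$confounder, cfg,
                          sex = cohort$covariates$sex,
                          gamma = cohort$truth$gamma)
  cohort$outcomes[[outcome_name]] <- out$outcome
  cohort$truth$outcomes[[outcome_name]] <-
    list(config = cfg, alpha = out$alpha, c0 = out$c0)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d individuals, %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  outcomes: %s\n", paste(names(x$outcomes), collapse = ", ")))
  cat(sprintf("  exposure: standardized (raw mean %.1f, SD %.1f)\n",
              mean(x$exposure_raw), stats::sd(x$exposure_raw)))
  invisible(x)
}
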