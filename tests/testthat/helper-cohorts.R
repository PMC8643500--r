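# Shared fixture builders. All fixtures are generated in code, seeded.

# hand-built cohort object with fully controlled columns
make_fake_cohort <- function(genotypes, exposure, outcomes,
                             exposure_raw = NULL, covariates = NULL,
                             gamma = NULL, ea = NULL, oa = NULL,
                             seed = 1L) {
  n <- length(exposure)
  m <- ncol(genotypes)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- paste0("rs", seq_len(m))
  if (is.null(ea)) ea <- rep("A", m)
  if (is.null(oa)) oa <- rep("G", m)
  attr(genotypes, "ea") <- ea
  attr(genotypes, "oa") <- oa
  attr(genotypes, "maf") <- colMeans(genotypes) / 2
  if (is.null(covariates))
    covariates <- data.frame(age = rep(50, n), sex = rep(0:1, length.out = n),
                             centre = factor(rep("c1", n)),
                             deprivation = rep(0, n),
                             smoking = factor(rep("never", n)))
  if (is.null(exposure_raw)) exposure_raw <- 26.8 + 4.6 * exposure
  if (is.null(gamma)) gamma <- rep(0, m)
  structure(list(
    genotypes = genotypes, exposure = exposure,
    exposure_raw = exposure_raw, covariates = covariates,
    outcomes = as.data.frame(outcomes), confounder = rep(0, n),
    truth = list(config = sim_config(n_individuals = max(n, 2), n_snps = max(m, 2),
                                     seed = seed),
                 gamma = gamma, alpha = rep(0, m),
                 maf = colMeans(genotypes) / 2, ea = ea, oa = oa,
                 c0 = NA_real_)
  ), class = "cohort")
}

# small harmonizable summary table pair with controllable quirks
make_stats_pair <- function(k = 8, seed = 1) {
  set.seed(seed)
  alleles <- t(replicate(k, sample(c("A", "C", "G", "T"), 2)))
  exp_stats <- data.frame(
    SNP = paste0("rs", 1:k), EA = alleles[, 1], OA = alleles[, 2],
    EAF = runif(k, 0.05, 0.95), BETA = rnorm(k, 0, 0.1),
    SE = runif(k, 0.005, 0.02), P = runif(k), N = 10000,
    stringsAsFactors = FALSE)
  swap <- runif(k) < 0.5
  out_stats <- exp_stats
  out_stats$EA[swap] <- exp_stats$OA[swap]
  out_stats$OA[swap] <- exp_stats$EA[swap]
  out_stats$EAF[swap] <- 1 - exp_stats$EAF[swap]
  out_stats$BETA <- 0.5 * exp_stats$BETA + rnorm(k, 0, 0.02)
  out_stats$BETA[swap] <- -out_stats$BETA[swap]
  out_stats$SE <- runif(k, 0.01, 0.03)
  list(exposure = exp_stats, outcome = out_stats)
}

mc_se <- function(x) stats::sd(x) / sqrt(length(x))
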