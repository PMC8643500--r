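#' Build a pipeline run configuration
#'
#' Encodes one analysis matrix: a simulated base cohort per exposure
#' definition (instrument set), a list of outcomes with their generative
#' settings, sex strata, the methods to run, and the seeds and bootstrap
#' sizes every stochastic step uses. Defaults give the "small" preset: a
#' 20 000-person cohort, a BMI-like exposure with 72 instruments
#' explaining 1.6\% of variance, plus weak favourable-like (h2 = 0.002)
#' and unfavourable-like (h2 = 0.006) instrument sets, one rare binary
#' depression-like outcome and one continuous well-being-like outcome.
#'
#' @param n_individuals Cohort size per exposure set.
#' @param exposures Named list: each element a list with fields `n_snps`
#'   and `h2`.
#' @param outcomes Named list: each element a list with fields `kind`
#'   (`"binary"`/`"continuous"`), `causal_coef`, and optionally
#'   `causal_function`, `prevalence`, `pleiotropy_mode`, `pleiotropy_sd`,
#'   `pleiotropy_mean`.
#' @param strata Subset of `c("all", "male", "female")`.
#' @param methods Subset of `c("observational", "tsls", "ivw", "egger",
#'   "wmedian", "pwmedian", "nonlinear")`.
#' @param split Two-sample split fraction.
#' @param n_boot Bootstrap draws for median estimators and the non-linear
#'   curve.
#' @param n_strata Strata for non-linear MR.
#' @param seed Master seed; all stage seeds derive from it.
#' @param bonferroni If TRUE the report adds a Bonferroni-adjusted p
#'   column across the emitted estimate rows.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_individuals = 20000L,
                       exposures = list(
                         bmi = list(n_snps = 72L, h2 = 0.016),
                         favourable = list(n_snps = 36L, h2 = 0.002),
                         unfavourable = list(n_snps = 38L, h2 = 0.006)),
                       outcomes = list(
                         depression = list(kind = "binary",
                                           causal_coef = 0.405,
                                           prevalence = 0.018),
                         wellbeing = list(kind = "continuous",
                                          causal_coef = -0.15)),
                       strata = "all",
                       methods = c("observational", "tsls", "ivw", "egger",
                                   "wmedian", "pwmedian", "nonlinear"),
                       split = 0.5,
                       n_boot = 100L,
                       n_strata = 10L,
                       seed = 1L,
                       bonferroni = FALSE) {
  strata <- match.arg(strata, c("all", "male", "female"),
                      several.ok = TRUE)
  methods <- match.arg(methods,
                       c("observational", "tsls", "ivw", "egger",
                         "wmedian", "pwmedian", "nonlinear"),
                       several.ok = TRUE)
  stopifnot(length(exposures) >= 1L, length(outcomes) >= 1L,
            !is.null(names(exposures)), !is.null(names(outcomes)))
  for (o in outcomes)
    if (!o$kind %in% c("binary", "continuous"))
      stop("outcome kind must be binary or continuous")
  structure(list(n_individuals = as.integer(n_individuals),
                 exposures = exposures, outcomes = outcomes,
                 strata = strata, methods = methods, split = split,
                 n_boot = as.integer(n_boot),
                 n_strata = as.integer(n_strata),
                 seed = as.integer(seed), bonferroni = bonferroni),
            class = "run_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path Config file path; keys are [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- read_config_file(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown run_config fields: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full analysis matrix
#'
#' Executes, per exposure set: cohort simulation, then per outcome and
#' stratum every requested method — observational regression, one-sample
#' 2SLS, the two-sample estimators on split-sample summary statistics,
#' and non-linear MR. Any failure in one analysis cell is caught, logged
#' and recorded as a row with status `"error"`; the rest of the matrix
#' proceeds. Writes `results.tsv` (one row per estimate), `strata.tsv`
#' (non-linear LACE tables), `diagnostics.tsv` (instrument strength per
#' exposure set) and `manifest.json` (config, derived seeds, config hash,
#' package version) to `out_dir` when given.
#'
#' @param config A [run_config()] object.
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with `results` (data.frame), `strata`,
#'   `diagnostics`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  srows <- list()
  drows <- list()
  add <- function(exposure, outcome, stratum, method, df) {
    df <- cbind(data.frame(exposure = exposure, outcome = outcome,
                           stratum = stratum, stringsAsFactors = FALSE),
                df)
    rows[[length(rows) + 1L]] <<- df
  }
  fail_row <- function(method, msg) {
    data.frame(method = method, scale = NA_character_, beta = NA_real_,
               se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p = NA_real_, n_instruments = NA_integer_,
               q_statistic = NA_real_, q_p = NA_real_,
               egger_intercept = NA_real_, egger_intercept_p = NA_real_,
               flags = "", status = "error", reason = msg,
               stringsAsFactors = FALSE)
  }
  ok_row <- function(est) {
    df <- as.data.frame(est)
    df$status <- "ok"; df$reason <- ""
    df
  }

  for (ei in seq_along(config$exposures)) {
    ename <- names(config$exposures)[ei]
    espec <- config$exposures[[ei]]
    base_seed <- seed_offset(config$seed, 100L * ei)
    cfg <- sim_config(n_individuals = config$n_individuals,
                      n_snps = espec$n_snps, exposure_h2 = espec$h2,
                      seed = base_seed)
    coh <- simulate_cohort(cfg)
    coh$outcomes$y <- NULL
    for (oi in seq_along(config$outcomes)) {
      oname <- names(config$outcomes)[oi]
      ospec <- config$outcomes[[oi]]
      over <- list(causal_coef = ospec$causal_coef,
                   outcome_kind = ospec$kind)
      if (!is.null(ospec$causal_function))
        over$causal_function <- ospec$causal_function
      if (!is.null(ospec$prevalence))
        over$binary_prevalence <- ospec$prevalence
      for (f in c("pleiotropy_mode", "pleiotropy_sd", "pleiotropy_mean"))
        if (!is.null(ospec[[f]])) over[[f]] <- ospec[[f]]
      coh <- do.call(add_outcome,
                     c(list(coh, oname, seed_offset(base_seed, 10L * oi)),
                       over))
    }
    grs <- cohort_grs(coh)
    strength <- instrument_strength(grs, coh$exposure)
    drows[[length(drows) + 1L]] <- data.frame(
      exposure = ename, r_squared = strength$r_squared,
      f_statistic = strength$f_statistic, n = strength$n,
      weak_flag = strength$weak_flag, stringsAsFactors = FALSE)

    for (oname in names(config$outcomes)) {
      okind <- config$outcomes[[oname]]$kind
      for (stratum in config$strata) {
        sub <- switch(stratum,
                      all = rep(TRUE, config$n_individuals),
                      male = coh$covariates$sex == 1,
                      female = coh$covariates$sex == 0)
        run_cell <- function(method, fn) {
          df <- tryCatch(ok_row(fn()),
                         error = function(e)
                           fail_row(method, conditionMessage(e)))
          add(ename, oname, stratum, method, df)
        }
        if ("observational" %in% config$methods)
          run_cell("observational", function() {
            covs <- if (stratum == "all")
              c("age", "sex", "centre", "deprivation", "smoking")
            else c("age", "centre", "deprivation", "smoking")
            est <- fit_observational(coh, oname, covariates = covs,
                                     stratum = stratum)
            if (est$status != "ok") stop("estimate withheld: ", est$status)
            df <- as.data.frame(est)[, c("method", "scale", "p")]
            df$beta <- est$beta; df$se <- est$se
            df$ci_low <- est$ci_low; df$ci_high <- est$ci_high
            df$n_instruments <- NA_integer_
            df$q_statistic <- NA_real_; df$q_p <- NA_real_
            df$egger_intercept <- NA_real_
            df$egger_intercept_p <- NA_real_
            df$flags <- ""
            df[, c("method", "scale", "beta", "se", "ci_low", "ci_high",
                   "p", "n_instruments", "q_statistic", "q_p",
                   "egger_intercept", "egger_intercept_p", "flags")]
          })
        if ("tsls" %in% config$methods)
          run_cell("2SLS", function()
            tsls(coh, oname, grs = grs, outcome_kind = okind,
                 subset = sub))
        two_sample <- intersect(config$methods,
                                c("ivw", "egger", "wmedian", "pwmedian"))
        if (length(two_sample) && stratum == "all") {
          ss <- cohort_to_summary_stats(coh, oname, split = config$split,
                                        seed = seed_offset(base_seed, 50L))
          h <- harmonize(ss)
          mr_scale <- if (okind == "binary") "log-odds per SD exposure"
                      else "outcome units per SD exposure"
          if ("ivw" %in% two_sample)
            run_cell("IVW", function() mr_ivw(wald_ratios(h),
                                              scale = mr_scale))
          if ("egger" %in% two_sample)
            run_cell("MR-Egger", function() mr_egger(h, scale = mr_scale))
          if ("wmedian" %in% two_sample)
            run_cell("Weighted median", function()
              mr_weighted_median(h, n_boot = config$n_boot,
                                 seed = seed_offset(base_seed, 51L),
                                 scale = mr_scale))
          if ("pwmedian" %in% two_sample)
            run_cell("Penalized weighted median", function()
              mr_penalized_weighted_median(
                h, n_boot = config$n_boot,
                seed = seed_offset(base_seed, 52L), scale = mr_scale))
        }
        if ("nonlinear" %in% config$methods && stratum == "all") {
          nl <- tryCatch(
            mr_nonlinear(coh$exposure, coh$outcomes[[oname]], grs,
                         n_strata = config$n_strata, outcome_kind = okind,
                         n_boot = config$n_boot,
                         seed = seed_offset(base_seed, 53L),
                         exposure_units = "SD exposure"),
            error = function(e) e)
          if (inherits(nl, "error")) {
            add(ename, oname, stratum, "nonlinear",
                fail_row("nonlinear", conditionMessage(nl)))
          } else {
            st <- nl$strata
            st$status <- ifelse(st$flag == "", "ok", "withheld")
            srows[[length(srows) + 1L]] <-
              cbind(data.frame(exposure = ename, outcome = oname,
                               stringsAsFactors = FALSE), st)
            if (is.null(nl$tests)) {
              bad <- nl$strata[nl$strata$flag != "", ]
              df <- fail_row("nonlinear",
                             sprintf("fewer than 3 unflagged strata (%s)",
                                     paste(unique(bad$flag),
                                           collapse = ", ")))
              df$status <- "withheld"
              add(ename, oname, stratum, "nonlinear", df)
            } else
              add(ename, oname, stratum, "nonlinear", {
                df <- fail_row("nonlinear (quadratic test)", "")
                df$status <- "ok"
                df$beta <- nl$tests$quadratic_test$slope
                df$se <- nl$tests$quadratic_test$se
                df$p <- nl$tests$quadratic_test$p
                df$q_statistic <- nl$tests$q_test$statistic
                df$q_p <- nl$tests$q_test$p
                df$scale <- "LACE slope per SD exposure"
                df
              })
          }
        }
      }
    }
  }

  results <- do.call(rbind, rows)
  strata_tab <- if (length(srows)) do.call(rbind, srows) else NULL
  diagnostics <- do.call(rbind, drows)
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("adipomr")),
                   n_results = nrow(results))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(results, file.path(out_dir, "results.tsv"))
    if (!is.null(strata_tab))
      write_tsv(strata_tab, file.path(out_dir, "strata.tsv"))
    write_tsv(diagnostics, file.path(out_dir, "diagnostics.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(results = results, strata = strata_tab,
                 diagnostics = diagnostics, manifest = manifest))
}

# stable hash of the configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
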