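#' Build a weighted genetic risk score from external variant weights
#'
#' `score_i = sum_j w_j d_ij` over the instrument SNPs, after aligning each
#' genotype column to the weight table's effect allele: where the weight's
#' effect allele equals the genotype's *other* allele the dosage is flipped
#' (`d -> 2 - d`). Weights are external discovery-study effect sizes (SD
#' units of exposure per allele), never re-estimated in the analysis sample,
#' to avoid winner's-curse bias. Variants whose alleles cannot be resolved
#' against the genotype labels are excluded with a logged reason. The score
#' is standardized to mean 0, SD 1 for use as an instrument in regressions.
#'
#' @param genotypes Dosage matrix with column names matching weight ids and
#'   attributes `ea`/`oa` giving per-column allele labels (as produced by
#'   [simulate_genotypes()] or [read_genotypes_vcf()]).
#' @param weights A data.frame of variant weights with columns `SNP`, `EA`,
#'   `OA`, `BETA` (see [read_variant_weights()]), or NULL to take the
#'   cohort's generating truth as the external weight set.
#' @return Standardized numeric score vector with attributes `raw` (the
#'   unstandardized score) and `exclusions` (data.frame of SNP, reason).
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 200, seed = 2))
#' grs <- build_grs(coh$genotypes, cohort_truth_weights(coh))
#' @export
build_grs <- function(genotypes, weights) {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)))
  need <- c("SNP", "EA", "OA", "BETA")
  if (!all(need %in% names(weights)))
    stop("weights must have columns ", paste(need, collapse = ", "))
  gea <- attr(genotypes, "ea")
  goa <- attr(genotypes, "oa")
  if (is.null(gea) || is.null(goa))
    stop("genotype matrix lacks `ea`/`oa` allele attributes")

  n <- nrow(genotypes)
  score <- numeric(n)
  excl <- list()
  used <- 0L
  for (k in seq_len(nrow(weights))) {
    id <- weights$SNP[k]
    j <- match(id, colnames(genotypes))
    if (is.na(j)) {
      excl[[length(excl) + 1L]] <- c(id, "missing_genotype"); next
    }
    w <- weights$BETA[k]
    if (weights$EA[k] == gea[j] && weights$OA[k] == goa[j]) {
      d <- genotypes[, j]
    } else if (weights$EA[k] == goa[j] && weights$OA[k] == gea[j]) {
      d <- 2 - genotypes[, j]
    } else {
      excl[[length(excl) + 1L]] <- c(id, "allele_mismatch"); next
    }
    score <- score + w * d
    used <- used + 1L
  }
  if (used == 0L) stop("no usable variants: all weights were excluded")
  if (stats::sd(score) == 0) {
    # degenerate score (e.g. all dosages equal): return it unstandardized;
    # instrument_strength() rejects it before any downstream use
    out <- score
    warning("zero-variance genetic risk score; returned unstandardized")
  } else {
    out <- (score - mean(score)) / stats::sd(score)
  }
  attr(out, "raw") <- score
  attr(out, "exclusions") <- if (length(excl)) {
    m <- do.call(rbind, excl)
    data.frame(SNP = m[, 1L], reason = m[, 2L], stringsAsFactors = FALSE)
  } else data.frame(SNP = character(), reason = character())
  attr(out, "n_variants") <- used
  out
}

#' Extract the generating truth of a simulated cohort as a weight table
#'
#' The realized per-allele SNP-exposure effects of a simulated cohort play
#' the role of an external discovery study's effect sizes (they are the
#' population values, free of winner's curse and of estimation noise from
#' the analysis sample).
#'
#' @param cohort A `cohort` object.
#' @return A variant-weight data.frame with columns `SNP`, `EA`, `OA`,
#'   `EAF`, `BETA`, `SE`.
#' @export
cohort_truth_weights <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  data.frame(SNP = colnames(cohort$genotypes),
             EA = cohort$truth$ea, OA = cohort$truth$oa,
             EAF = cohort$truth$maf,
             BETA = cohort$truth$gamma, SE = 0,
             stringsAsFactors = FALSE)
}

#' Convenience: standardized genetic risk score for a cohort
#'
#' @param cohort A `cohort` object.
#' @param weights Optional external weight table; defaults to the cohort's
#'   generating truth via [cohort_truth_weights()].
#' @return As [build_grs()].
#' @export
cohort_grs <- function(cohort, weights = NULL) {
  if (is.null(weights)) weights <- cohort_truth_weights(cohort)
  build_grs(cohort$genotypes, weights)
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) complement_allele(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns two per-variant association tables to a common allele frame and
#' then to the exposure-raising orientation, the convention under which
#' every variant's effect allele is the one associated with higher
#' exposure. Steps per variant: (1) match by id — unmatched variants are
#' excluded; (2) align alleles, sign-flipping the outcome beta (and
#' reflecting EAF) when the tables name effect alleles on opposite
#' assignments, allowing strand (complement) resolution; palindromic
#' variants (A/T or C/G) with effect-allele frequency in [0.42, 0.58] are
#' excluded as strand-ambiguous; (3) where the exposure beta is negative,
#' flip both betas (and the allele labels) so all exposure betas end up
#' >= 0. The operation is idempotent: harmonizing an already harmonized set
#' changes nothing.
#'
#' @param exposure_stats,outcome_stats Data.frames with columns `SNP`,
#'   `EA`, `OA`, `EAF`, `BETA`, `SE` (as read by [read_gwas_tsv()]), or a
#'   single joint `summary_stats` table from [cohort_to_summary_stats()]
#'   passed as `exposure_stats` with `outcome_stats = NULL`.
#' @param palindromic_window EAF interval within which palindromic variants
#'   are dropped as ambiguous.
#' @return Object of class `harmonized_set`: data.frame of retained
#'   variants (`SNP`, `EA`, `OA`, `EAF`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`) with attribute `excluded` (data.frame of
#'   SNP, reason). Every input variant appears exactly once, either
#'   retained or excluded.
#' @export
harmonize <- function(exposure_stats, outcome_stats = NULL,
                      palindromic_window = c(0.42, 0.58)) {
  if (is.null(outcome_stats)) {
    h <- joint_to_harmonized(exposure_stats)
    return(orient_exposure_raising(h, palindromic_window))
  }
  for (nm in c("SNP", "EA", "OA", "BETA", "SE"))
    if (!nm %in% names(exposure_stats) || !nm %in% names(outcome_stats))
      stop("summary tables need columns SNP, EA, OA, EAF, BETA, SE")

  rows <- list()
  excl <- list()
  out_idx <- match(exposure_stats$SNP, outcome_stats$SNP)
  for (k in seq_len(nrow(exposure_stats))) {
    id <- exposure_stats$SNP[k]
    j <- out_idx[k]
    if (is.na(j)) { excl[[length(excl) + 1L]] <- c(id, "unmatched"); next }
    ea_x <- toupper(exposure_stats$EA[k]); oa_x <- toupper(exposure_stats$OA[k])
    ea_y <- toupper(outcome_stats$EA[j]);  oa_y <- toupper(outcome_stats$OA[j])
    b_y <- outcome_stats$BETA[j]
    if (ea_y == ea_x && oa_y == oa_x) {
      flip <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      flip <- TRUE
    } else if (complement_allele(ea_y) == ea_x &&
               complement_allele(oa_y) == oa_x) {
      flip <- FALSE
    } else if (complement_allele(ea_y) == oa_x &&
               complement_allele(oa_y) == ea_x) {
      flip <- TRUE
    } else {
      excl[[length(excl) + 1L]] <- c(id, "allele_mismatch"); next
    }
    eaf <- exposure_stats$EAF[k]
    if (is_palindromic(ea_x, oa_x) && !is.na(eaf) &&
        eaf >= palindromic_window[1] && eaf <= palindromic_window[2]) {
      excl[[length(excl) + 1L]] <- c(id, "palindromic_ambiguous"); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      SNP = id, EA = ea_x, OA = oa_x, EAF = eaf,
      beta_exposure = exposure_stats$BETA[k],
      se_exposure = exposure_stats$SE[k],
      beta_outcome = if (flip) -b_y else b_y,
      se_outcome = outcome_stats$SE[j],
      stringsAsFactors = FALSE)
  }
  # outcome-only variants are unmatched too (every variant accounted for)
  only_out <- setdiff(outcome_stats$SNP, exposure_stats$SNP)
  for (id in only_out) excl[[length(excl) + 1L]] <- c(id, "unmatched")

  h <- if (length(rows)) do.call(rbind, rows) else
    data.frame(SNP = character(), EA = character(), OA = character(),
               EAF = numeric(), beta_exposure = numeric(),
               se_exposure = numeric(), beta_outcome = numeric(),
               se_outcome = numeric(), stringsAsFactors = FALSE)
  attr(h, "excluded") <- exclusion_frame(excl)
  orient_exposure_raising(h, palindromic_window)
}

exclusion_frame <- function(excl) {
  if (length(excl)) {
    m <- do.call(rbind, excl)
    data.frame(SNP = m[, 1L], reason = m[, 2L], stringsAsFactors = FALSE)
  } else data.frame(SNP = character(), reason = character(),
                    stringsAsFactors = FALSE)
}

# a joint summary_stats table is already on one allele frame; only the
# palindromic filter and the exposure-raising orientation apply
joint_to_harmonized <- function(ss) {
  need <- c("SNP", "EA", "OA", "EAF", "beta_exposure", "se_exposure",
            "beta_outcome", "se_outcome")
  if (!all(need %in% names(ss)))
    stop("joint table needs columns ", paste(need, collapse = ", "))
  h <- as.data.frame(ss)[, need]
  attr(h, "excluded") <- exclusion_frame(list())
  h
}

orient_exposure_raising <- function(h, palindromic_window) {
  excl0 <- attr(h, "excluded")
  # palindromic filter (idempotent: re-applying removes nothing new)
  pal <- is_palindromic(h$EA, h$OA) & !is.na(h$EAF) &
    h$EAF >= palindromic_window[1] & h$EAF <= palindromic_window[2]
  if (any(pal)) {
    excl0 <- rbind(excl0, data.frame(SNP = h$SNP[pal],
                                     reason = "palindromic_ambiguous",
                                     stringsAsFactors = FALSE))
    h <- h[!pal, , drop = FALSE]
  }
  neg <- !is.na(h$beta_exposure) & h$beta_exposure < 0
  if (any(neg)) {
    tmp <- h$EA[neg]; h$EA[neg] <- h$OA[neg]; h$OA[neg] <- tmp
    h$EAF[neg] <- 1 - h$EAF[neg]
    h$beta_exposure[neg] <- -h$beta_exposure[neg]
    h$beta_outcome[neg] <- -h$beta_outcome[neg]
  }
  rownames(h) <- NULL
  attr(h, "excluded") <- excl0
  class(h) <- c("harmonized_set", "data.frame")
  h
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized summary set: %d variants retained, %d excluded\n",
              nrow(x), nrow(attr(x, "excluded"))))
  ex <- attr(x, "excluded")
  if (nrow(ex)) {
    tb <- table(ex$reason)
    for (r in names(tb)) cat(sprintf("    %s: %d\n", r, tb[[r]]))
  }
  print.data.frame(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Instrument strength: variance explained and F-statistic
#'
#' R^2 is the variance of the exposure explained by the genetic score (from
#' the simple regression of exposure on score) and the F-statistic is
#' `R^2 (n - 2) / (1 - R^2)`. An F-statistic below 10 is the conventional
#' marker of weak-instrument bias and sets `weak_flag`.
#'
#' @param grs Genetic risk score vector (or any single instrument).
#' @param exposure Exposure vector, same individuals.
#' @return List with `r_squared`, `f_statistic`, `n`, `weak_flag`.
#' @examples
#' instrument_strength_from_r2(0.016, 145668)
#' @export
instrument_strength <- function(grs, exposure) {
  stopifnot(length(grs) == length(exposure))
  n <- length(grs)
  if (n <= 2) stop("need n > 2")
  if (stats::sd(grs) == 0) stop("zero-variance score")
  r2 <- stats::cor(grs, exposure)^2
  instrument_strength_from_r2(r2, n)
}

#' @rdname instrument_strength
#' @param r2 Variance explained.
#' @param n Sample size.
#' @export
instrument_strength_from_r2 <- function(r2, n) {
  f <- r2 * (n - 2) / (1 - r2)
  list(r_squared = r2, f_statistic = f, n = n, weak_flag = f < 10)
}
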