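#' Read and write GWAS summary-statistic tables
#'
#' Tab-separated files with the conventional header
#' `SNP  EA  OA  EAF  BETA  SE  P  N` (variant id, effect allele, other
#' allele, effect-allele frequency, per-allele effect, standard error,
#' p-value, sample size). `read_gwas_tsv()` validates that SEs are strictly
#' positive and alleles are single characters from A/C/G/T.
#'
#' @param path File path.
#' @return `read_gwas_tsv`: a data.frame with the columns above.
#' @export
read_gwas_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("GWAS summary file lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$SE) | df$SE <= 0))
    stop("all SEs must be strictly positive")
  ok <- grepl("^[ACGT]$", toupper(df$EA)) & grepl("^[ACGT]$", toupper(df$OA))
  if (any(!ok))
    stop("alleles must be single characters from {A,C,G,T}")
  df$EA <- toupper(df$EA); df$OA <- toupper(df$OA)
  df
}

#' @rdname read_gwas_tsv
#' @param ss A `summary_stats` table from [cohort_to_summary_stats()].
#' @param which Which association to export: `"exposure"` or `"outcome"`.
#' @export
write_gwas_tsv <- function(ss, path, which = c("exposure", "outcome")) {
  which <- match.arg(which)
  pick <- function(nm) ss[[paste0(nm, "_", which)]]
  out <- data.frame(SNP = ss$SNP, EA = ss$EA, OA = ss$OA, EAF = ss$EAF,
                    BETA = pick("beta"), SE = pick("se"), P = pick("p"),
                    N = pick("n"), stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}

#' Read a variant-weight table
#'
#' Tab-separated instrument table with header `SNP EA OA EAF BETA SE`
#' (the external discovery-study per-allele effect on the exposure, in SD
#' units, and its SE). A small synthetic example table ships with the
#' package (see the example).
#'
#' @param path File path.
#' @return Data.frame of variant weights.
#' @examples
#' w <- read_variant_weights(system.file("extdata",
#'                                       "synthetic_bmi_weights.tsv",
#'                                       package = "adipomr"))
#' head(w)
#' @export
read_variant_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "EA", "OA", "EAF", "BETA", "SE")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weight table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$BETA))) stop("weights must be finite")
  if (any(df$EAF <= 0 | df$EAF >= 1)) stop("EAF must lie in (0, 1)")
  df$EA <- toupper(df$EA); df$OA <- toupper(df$OA)
  df
}

#' Write a simulated cohort to tab-separated text
#'
#' Writes `<stem>_phenotypes.tsv` (exposure, covariates, outcomes),
#' `<stem>_genotypes.tsv` (dosages) and a JSON sidecar
#' `<stem>_truth.json` holding the generating configuration and realized
#' effect sizes, so a written cohort carries its own ground truth.
#'
#' @param cohort A `cohort` object.
#' @param stem Output path stem.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "cohort"))
  ph <- cbind(data.frame(exposure = cohort$exposure,
                         exposure_raw = cohort$exposure_raw),
              cohort$covariates, cohort$outcomes)
  p1 <- paste0(stem, "_phenotypes.tsv")
  p2 <- paste0(stem, "_genotypes.tsv")
  p3 <- paste0(stem, "_truth.json")
  write_tsv(ph, p1)
  write_tsv(as.data.frame(cohort$genotypes), p2)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(phenotypes = p1, genotypes = p2, truth = p3))
}

# deterministic TSV writer (fixed numeric formatting => byte-identical
# reruns under identical seeds)
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Extracts per-sample dosages from the `DS` FORMAT field when present,
#' otherwise counts ALT alleles in `GT`. Returns the dosage matrix in the
#' orientation used throughout the package (effect allele = ALT), with
#' `ea`/`oa` attributes from the ALT/REF columns. Requires the `vcfR`
#' package.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return Numeric matrix (individuals x variants) with allele attributes.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  has_ds <- "DS" %in% unlist(strsplit(unique(v@gt[, "FORMAT"]), ":"))
  if (has_ds) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, c(1, 2), function(s) {
      if (is.na(s)) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0)
    })
  }
  g <- t(d)  # individuals x variants
  colnames(g) <- fix[, "ID"]
  attr(g, "ea") <- unname(fix[, "ALT"])
  attr(g, "oa") <- unname(fix[, "REF"])
  g
}
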