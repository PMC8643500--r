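#' Format an effect estimate for tabular reporting
#'
#' Renders `beta` and `se` as `"est (lo, hi)"` with a normal-theory 95\%
#' CI, exponentiating to the odds-ratio scale when `exp = TRUE` (so a
#' log-odds 0.405 with SE 0.135 prints as `"1.50 (1.15, 1.95)"`). Missing
#' estimates render as an em-dash, never as an empty cell.
#'
#' @param beta,se Estimate and standard error.
#' @param exp Exponentiate onto the OR scale?
#' @param digits Decimal places.
#' @return Character scalar.
#' @examples
#' format_effect(0.405, 0.135, exp = TRUE)
#' @export
format_effect <- function(beta, se, exp = FALSE, digits = 2) {
  if (is.na(beta) || is.na(se)) return("—")
  z <- stats::qnorm(0.975)
  v <- c(beta, beta - z * se, beta + z * se)
  if (exp) v <- exp(v)
  sprintf("%.*f (%.*f, %.*f)", digits, v[1L], digits, v[2L], digits, v[3L])
}

#' Summarize pipeline results as wide per-outcome tables
#'
#' Reshapes the tidy results of [run_pipeline()] into one wide table per
#' outcome: a row per (exposure set, stratum), a column per method holding
#' the formatted effect with CI — odds ratios for binary-scale estimates,
#' raw slopes otherwise — plus the p-value columns. Cells for failed or
#' withheld analyses hold an em-dash. Optionally appends a
#' Bonferroni-adjusted p column across all emitted rows (the primary
#' analysis reports nominal p-values; the adjusted column is clearly
#' labelled as such).
#'
#' @param run A list returned by [run_pipeline()] (or its `results`
#'   data.frame).
#' @param bonferroni Add a `p_bonferroni` column?
#' @return Named list of data.frames, one per outcome.
#' @export
report_results <- function(run, bonferroni = FALSE) {
  res <- if (is.data.frame(run)) run else run$results
  if (bonferroni) {
    res$p_bonferroni <- stats::p.adjust(res$p, method = "bonferroni")
  }
  out <- list()
  for (oname in unique(res$outcome)) {
    r <- res[res$outcome == oname, , drop = FALSE]
    cells <- unique(r[, c("exposure", "stratum")])
    tab <- cells
    for (m in unique(r$method)) {
      col <- vapply(seq_len(nrow(cells)), function(i) {
        row <- r[r$exposure == cells$exposure[i] &
                   r$stratum == cells$stratum[i] & r$method == m, ]
        if (nrow(row) == 0L || row$status[1L] != "ok") return("—")
        format_effect(row$beta[1L], row$se[1L],
                      exp = grepl("odds", row$scale[1L]))
      }, character(1))
      pcol <- vapply(seq_len(nrow(cells)), function(i) {
        row <- r[r$exposure == cells$exposure[i] &
                   r$stratum == cells$stratum[i] & r$method == m, ]
        if (nrow(row) == 0L || row$status[1L] != "ok") return(NA_real_)
        row$p[1L]
      }, numeric(1))
      tab[[m]] <- col
      tab[[paste0(m, "_p")]] <- pcol
    }
    out[[oname]] <- tab
  }
  out
}
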