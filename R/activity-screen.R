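#' Read a kinase-panel residual-activity table
#'
#' Residual activity is the treated sample's kinase activity as percent of
#' the untreated blank (blank = 100); lower means stronger inhibition.
#' Rows are validated: activity must be finite and non-negative,
#' concentration positive, and (gene_symbol, concentration) unique.
#'
#' @param path CSV with columns `kinase_name`, `gene_symbol`, `entrez_id`,
#'   `concentration` (µg/mL), `activity_pct`.
#' @return Validated data frame of panel measurements.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) svt_stop(paste("no such file:", path))
  if (file.size(path) == 0) svt_stop(paste("empty panel file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_panel(df)
}

validate_panel <- function(df) {
  assert_cols(df, c("kinase_name", "gene_symbol", "entrez_id",
                    "concentration", "activity_pct"), "panel table")
  if (!nrow(df)) svt_stop("panel table has no measurements")
  if (any(!is.finite(df$activity_pct)) || any(df$activity_pct < 0)) {
    bad <- df$gene_symbol[!is.finite(df$activity_pct) | df$activity_pct < 0]
    svt_stop(paste("negative or non-finite activity for:",
                   paste(bad, collapse = ", ")))
  }
  if (any(df$concentration <= 0)) svt_stop("concentrations must be positive")
  dup <- duplicated(df[, c("gene_symbol", "concentration")])
  if (any(dup)) {
    svt_stop(paste("duplicate (gene_symbol, concentration) measurement(s):",
                   paste(df$gene_symbol[dup], collapse = ", ")))
  }
  df
}

#' Call active kinases at a residual-activity threshold
#'
#' A kinase is active when its residual activity is at (inclusive, the
#' default) or below the threshold. The 80% default reflects the
#' weak-interaction pharmacology of multi-component preparations; classical
#' single-compound conventions would use 70% or lower.
#'
#' @param panel measurements at a single concentration (see [read_panel()]).
#' @param threshold residual-activity threshold, default 80.
#' @param inclusive if `TRUE` (default) activity equal to the threshold is
#'   active.
#' @return The active subset, sorted by ascending activity.
#' @export
screen_active <- function(panel, threshold = 80, inclusive = TRUE) {
  panel <- validate_panel(panel)
  if (length(unique(panel$concentration)) != 1L) {
    svt_stop("screen_active expects measurements at a single concentration")
  }
  keep <- if (inclusive) panel$activity_pct <= threshold
          else panel$activity_pct < threshold
  out <- panel[keep, , drop = FALSE]
  out <- out[order(out$activity_pct, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select actives for retesting at a higher concentration
#'
#' Keeps actives whose residual activity is strictly (default) below the
#' retest cutoff.
#'
#' @param actives output of [screen_active()].
#' @param cutoff retest cutoff, default 70.
#' @param strict strictly-below (default) vs at-or-below.
#' @return The retest subset (same columns, activity-sorted).
#' @export
select_retest <- function(actives, cutoff = 70, strict = TRUE) {
  if (!nrow(actives)) return(actives)
  keep <- if (strict) actives$activity_pct < cutoff
          else actives$activity_pct <= cutoff
  out <- actives[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag dose-dependent inhibition between two concentrations
#'
#' A kinase is flagged when inhibition deepens at the higher dose by at
#' least `margin` percentage points: `activity_high <= activity_low -
#' margin`. With `margin = 0` every strict decrease is flagged; flags are
#' anti-monotone in `margin`. A kinase with a missing activity at either
#' concentration gets an `NA` flag; a kinase absent from one panel is an
#' error.
#'
#' @param low_conc_panel,high_conc_panel panel data frames covering the same
#'   kinases at the lower/higher concentration.
#' @param margin minimum decrease in percentage points, default 10.
#' @return data frame: `gene_symbol`, `activity_low`, `activity_high`,
#'   `dose_dependent` (logical, `NA` when a value is missing).
#' @export
flag_dose_dependent <- function(low_conc_panel, high_conc_panel, margin = 10) {
  assert_cols(low_conc_panel, c("gene_symbol", "activity_pct"), "low-dose panel")
  assert_cols(high_conc_panel, c("gene_symbol", "activity_pct"), "high-dose panel")
  only_low <- setdiff(low_conc_panel$gene_symbol, high_conc_panel$gene_symbol)
  only_high <- setdiff(high_conc_panel$gene_symbol, low_conc_panel$gene_symbol)
  if (length(only_low) || length(only_high)) {
    svt_stop(paste("kinase(s) missing from one panel:",
                   paste(c(only_low, only_high), collapse = ", ")))
  }
  genes <- sort(unique(low_conc_panel$gene_symbol))
  lo <- low_conc_panel$activity_pct[match(genes, low_conc_panel$gene_symbol)]
  hi <- high_conc_panel$activity_pct[match(genes, high_conc_panel$gene_symbol)]
  # a zero margin still requires a strict decrease: unchanged activity is
  # never dose-dependent
  data.frame(gene_symbol = genes, activity_low = lo, activity_high = hi,
             dose_dependent = (hi <= lo - margin) & (hi < lo),
             stringsAsFactors = FALSE)
}

#' Run the full panel screen
#'
#' Convenience wrapper: active call, retest selection and (when a
#' high-concentration panel is supplied) dose-dependence flags, with the
#' thresholds echoed in the result for the run manifest.
#'
#' @param panel low-concentration panel data frame.
#' @param high_panel optional high-concentration panel for the retested
#'   kinases.
#' @param active_threshold,inclusive passed to [screen_active()].
#' @param retest_cutoff,strict passed to [select_retest()].
#' @param dose_margin passed to [flag_dose_dependent()].
#' @return list of class `screen_result`: `actives`, `retest`, `dose_flags`
#'   (or `NULL`), `thresholds`.
#' @export
run_screen <- function(panel, high_panel = NULL, active_threshold = 80,
                       inclusive = TRUE, retest_cutoff = 70, strict = TRUE,
                       dose_margin = 10) {
  if (retest_cutoff > active_threshold) {
    svt_config_error("retest cutoff cannot exceed the active threshold")
  }
  actives <- screen_active(panel, active_threshold, inclusive)
  retest <- select_retest(actives, retest_cutoff, strict)
  flags <- NULL
  if (!is.null(high_panel)) {
    flags <- flag_dose_dependent(
      retest[, c("gene_symbol", "activity_pct")],
      high_panel[high_panel$gene_symbol %in% retest$gene_symbol,
                 c("gene_symbol", "activity_pct"), drop = FALSE],
      margin = dose_margin)
  }
  structure(list(actives = actives, retest = retest, dose_flags = flags,
                 thresholds = list(active_threshold = active_threshold,
                                   inclusive = inclusive,
                                   retest_cutoff = retest_cutoff,
                                   strict = strict,
                                   dose_margin = dose_margin)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result: %d active (<= %g%s), %d for retest (%s %g)%s>\n",
              nrow(x$actives), x$thresholds$active_threshold,
              if (x$thresholds$inclusive) ", inclusive" else "",
              nrow(x$retest), if (x$thresholds$strict) "<" else "<=",
              x$thresholds$retest_cutoff,
              if (is.null(x$dose_flags)) "" else
                sprintf(", %d dose-dependent",
                        sum(x$dose_flags$dose_dependent, na.rm = TRUE))))
  invisible(x)
}
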