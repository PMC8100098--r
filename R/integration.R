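#' Merge known and predicted target tables with provenance
#'
#' Targets annotated in public databases ("known") and targets from the
#' multi-voting similarity ensemble ("predicted") are merged into one record
#' set; a target appearing in both sources gets provenance `"common"`.
#' Identity is by gene symbol after optional mapping through a user-supplied
#' two-column table (replacing proprietary annotation services); unmapped
#' names are logged and dropped, or abort under `strict`.
#'
#' @param known,predicted either character vectors of target names, or data
#'   frames with a `target_name` column and optionally `compound_id`.
#' @param symbol_map optional data frame (`raw_name`, `symbol`) or path to a
#'   two-column TSV; applied to both inputs.
#' @param kinase_vocabulary optional data frame from
#'   [read_kinase_vocabulary()]; sets `is_kinase` and `entrez_id`.
#' @param strict abort on unmappable names instead of dropping them.
#' @return `data.frame` of class `target_records` with columns `target_id`,
#'   `entrez_id`, `is_kinase`, `provenance` (`known`/`predicted`/`common`),
#'   `n_supporting_compounds`.
#' @export
integrate_targets <- function(known, predicted, symbol_map = NULL,
                              kinase_vocabulary = NULL, strict = FALSE) {
  k <- normalize_target_input(known, symbol_map, strict, "known")
  p <- normalize_target_input(predicted, symbol_map, strict, "predicted")
  k_ids <- unique(k$target_name)
  p_ids <- unique(p$target_name)
  all_ids <- sort(union(k_ids, p_ids))
  prov <- ifelse(all_ids %in% k_ids & all_ids %in% p_ids, "common",
                 ifelse(all_ids %in% k_ids, "known", "predicted"))
  support <- vapply(all_ids, function(t) {
    length(unique(c(k$compound_id[k$target_name == t],
                    p$compound_id[p$target_name == t])))
  }, integer(1))
  entrez <- rep(NA_integer_, length(all_ids))
  is_kin <- rep(NA, length(all_ids))
  if (!is.null(kinase_vocabulary)) {
    m <- match(all_ids, kinase_vocabulary$gene_symbol)
    entrez <- kinase_vocabulary$entrez_id[m]
    is_kin <- !is.na(m)
  }
  out <- data.frame(target_id = all_ids, entrez_id = entrez,
                    is_kinase = is_kin, provenance = prov,
                    n_supporting_compounds = support,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("target_records", "data.frame")
  out
}

normalize_target_input <- function(x, symbol_map, strict, what) {
  if (is.character(x)) {
    x <- data.frame(target_name = x,
                    compound_id = rep(NA_character_, length(x)),
                    stringsAsFactors = FALSE)
  }
  assert_cols(x, "target_name", paste(what, "target table"))
  if (!"compound_id" %in% names(x)) x$compound_id <- NA_character_
  if (!is.null(symbol_map)) {
    if (is.character(symbol_map)) {
      symbol_map <- read.delim(symbol_map, stringsAsFactors = FALSE)
    }
    assert_cols(symbol_map, c("raw_name", "symbol"), "symbol map")
    m <- match(x$target_name, symbol_map$raw_name)
    unmapped <- is.na(m) & !(x$target_name %in% symbol_map$symbol)
    if (any(unmapped)) {
      msg <- sprintf("%d unmappable %s target name(s): %s", sum(unmapped), what,
                     paste(unique(x$target_name[unmapped]), collapse = ", "))
      if (strict) svt_stop(msg)
      svt_log(msg)
      x <- x[!unmapped, , drop = FALSE]
      m <- m[!unmapped]
    }
    x$target_name <- ifelse(is.na(m), x$target_name, symbol_map$symbol[m])
  }
  x
}

#' Partition counts for an integrated target set
#'
#' Counts follow the inclusive convention of published intersection tables:
#' the "known" and "predicted" counts each include the common subset, so
#' `total = known + predicted - common` (inclusion-exclusion).
#'
#' @param records a `target_records` data frame from [integrate_targets()].
#' @param kinase_only restrict to records with `is_kinase == TRUE`.
#' @return data frame with one row and columns `known` (incl. common),
#'   `predicted` (incl. common), `common`, `total`.
#' @export
partition_counts <- function(records, kinase_only = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records)) assert_cols(records, "provenance", "target records")
  if (kinase_only && nrow(records)) {
    records <- records[!is.na(records$is_kinase) & records$is_kinase, , drop = FALSE]
  }
  n_common <- sum(records$provenance == "common")
  n_known <- sum(records$provenance == "known") + n_common
  n_pred <- sum(records$provenance == "predicted") + n_common
  data.frame(known = n_known, predicted = n_pred, common = n_common,
             total = n_known + n_pred - n_common)
}

#' Validation accuracy by provenance class
#'
#' For each provenance row (known, predicted, common — each inclusive of the
#' common subset — plus total), reports how many targets were tested in the
#' activity panel, how many were active, and the accuracy
#' `100 * active / tested` rounded half-up to one decimal. A row with zero
#' tested targets gets an undefined (`NA`) accuracy, never 0.
#'
#' @param records a `target_records` data frame.
#' @param tested character vector of target ids assayed in the panel (must be
#'   a subset of `records$target_id`).
#' @param active character vector of target ids called active (subset of
#'   `tested`).
#' @return data frame with columns `target_source`, `n_targets`, `n_tested`,
#'   `n_active`, `accuracy_pct`.
#' @export
accuracy_summary <- function(records, tested, active) {
  stopifnot(is.data.frame(records))
  assert_cols(records, c("target_id", "provenance"), "target records")
  if (length(setdiff(tested, records$target_id))) {
    svt_stop("tested targets must be a subset of the integrated records")
  }
  if (length(setdiff(active, tested))) {
    svt_stop("active targets must be a subset of the tested targets")
  }
  groups <- list(
    known = records$target_id[records$provenance %in% c("known", "common")],
    predicted = records$target_id[records$provenance %in% c("predicted", "common")],
    common = records$target_id[records$provenance == "common"],
    total = records$target_id
  )
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    n_t <- length(intersect(ids, tested))
    n_a <- length(intersect(ids, active))
    data.frame(target_source = g, n_targets = length(ids), n_tested = n_t,
               n_active = n_a,
               accuracy_pct = if (n_t == 0) NA_real_ else
                 round_half_up(100 * n_a / n_t, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write integrated target records as TSV
#' @param records a `target_records` data frame.
#' @param path output path.
#' @export
write_target_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reconstruct a placeholder record set from inclusive partition counts;
# used to exercise count/accuracy arithmetic when only printed totals exist
records_from_counts <- function(known, predicted, common,
                                prefix = c(known = "K", predicted = "P",
                                           common = "C")) {
  if (common > known || common > predicted) {
    svt_stop("common count cannot exceed either inclusive count")
  }
  ids <- c(
    if (known - common > 0) paste0(prefix[["known"]], seq_len(known - common)),
    if (predicted - common > 0) paste0(prefix[["predicted"]], seq_len(predicted - common)),
    if (common > 0) paste0(prefix[["common"]], seq_len(common))
  )
  prov <- c(rep("known", known - common), rep("predicted", predicted - common),
            rep("common", common))
  out <- data.frame(target_id = ids, entrez_id = NA_integer_, is_kinase = TRUE,
                    provenance = prov, n_supporting_compounds = NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("target_records", "data.frame")
  out
}
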