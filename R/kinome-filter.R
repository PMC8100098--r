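#' Read a kinase vocabulary file
#'
#' One gene symbol and Entrez id per line (TSV with header
#' `gene_symbol<TAB>entrez_id`). The packaged vocabulary covering the kinome
#' panel ships in `extdata/kinase_vocabulary.tsv`.
#'
#' @param path vocabulary file; defaults to the packaged one.
#' @return data frame with columns `gene_symbol`, `entrez_id`.
#' @export
read_kinase_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "kinase_vocabulary.tsv",
                                package = "seavote")
  if (!nzchar(path) || !file.exists(path)) svt_stop("kinase vocabulary file not found")
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("gene_symbol", "entrez_id"), "kinase vocabulary")
  if (!nrow(df)) svt_stop("empty kinase vocabulary")
  df
}

new_kinome_table <- function(predictions, source, metadata = list()) {
  structure(list(predictions = predictions, source = source,
                 metadata = metadata),
            class = "kinome_prediction_table")
}

#' @export
print.kinome_prediction_table <- function(x, ...) {
  cat(sprintf("<kinome predictions (%s): %d compounds, %d distinct kinases>\n",
              x$source, length(x$predictions),
              length(unique(unlist(x$predictions)))))
  invisible(x)
}

#' Load per-compound kinase predictions from an external tool export
#'
#' The kinome stage contract is "a set of predicted kinases per compound";
#' it is satisfied either by an export from an external predictor (e.g. a
#' deep kinome-profiling model) loaded here, or by the built-in similarity
#' surrogate ([surrogate_predict()]). Identifiers outside the declared
#' vocabulary are logged and dropped.
#'
#' @param path TSV with columns `compound_id`, `kinase_id` (optionally
#'   `score`).
#' @param vocabulary data frame from [read_kinase_vocabulary()], or a path.
#' @param compounds optional character vector: every listed compound gets an
#'   entry (empty if absent from the file), making the table complete for a
#'   filtering call.
#' @return A `kinome_prediction_table`.
#' @export
load_kinome_predictions <- function(path, vocabulary, compounds = NULL) {
  if (!file.exists(path)) svt_stop(paste("no such file:", path))
  if (is.character(vocabulary)) vocabulary <- read_kinase_vocabulary(vocabulary)
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("compound_id", "kinase_id"), "kinome prediction table")
  unknown <- !(df$kinase_id %in% vocabulary$gene_symbol)
  if (any(unknown)) {
    svt_log(sprintf("dropped %d prediction row(s) with kinase ids outside the vocabulary: %s",
                    sum(unknown), paste(unique(df$kinase_id[unknown]), collapse = ", ")))
    df <- df[!unknown, , drop = FALSE]
  }
  preds <- lapply(split(df$kinase_id, df$compound_id), function(k) sort(unique(k)))
  for (cid in setdiff(compounds, names(preds))) preds[[cid]] <- character(0)
  new_kinome_table(preds, source = "external_table",
                   metadata = list(path = path))
}

#' Similarity surrogate for an external kinome predictor
#'
#' Stands in for the external deep model: a kinase is predicted for a
#' compound iff the maximum Tanimoto similarity between the compound and any
#' of that kinase's reference ligands reaches `tc_cutoff`. Deterministic.
#'
#' @param compound [fp_set] of the compound's fingerprint(s).
#' @param kinase_reference a [sea_reference] whose targets are all kinases.
#' @param tc_cutoff Tanimoto cutoff, default 0.57.
#' @return Sorted character vector of predicted kinase ids.
#' @export
surrogate_predict <- function(compound, kinase_reference, tc_cutoff = 0.57) {
  stopifnot(inherits(compound, "fp_set"), inherits(kinase_reference, "sea_reference"))
  if (!length(kinase_reference$sets)) svt_stop("empty kinase reference")
  hit <- vapply(kinase_reference$sets, function(s) {
    max(tanimoto_matrix(compound, s)) >= tc_cutoff
  }, logical(1))
  sort(kinase_reference$target_ids[hit])
}

#' Build a surrogate prediction table for a compound set
#'
#' @param compounds named list of [fp_set] objects, one per compound.
#' @inheritParams surrogate_predict
#' @return A `kinome_prediction_table` with `source = "surrogate"`.
#' @export
surrogate_predict_table <- function(compounds, kinase_reference, tc_cutoff = 0.57) {
  preds <- lapply(compounds, surrogate_predict, kinase_reference = kinase_reference,
                  tc_cutoff = tc_cutoff)
  new_kinome_table(preds, source = "surrogate",
                   metadata = list(tc_cutoff = tc_cutoff,
                                   kind = kinase_reference$kind))
}

#' Restrict candidate targets to each compound's predicted kinases
#'
#' Per compound, a candidate target is kept iff it is in that compound's
#' predicted kinase set. Never adds targets, and is idempotent.
#'
#' @param candidates named list: compound id -> character vector of candidate
#'   target ids.
#' @param table a `kinome_prediction_table`.
#' @param strict if `TRUE`, a compound missing from the table aborts;
#'   otherwise it is treated as an empty prediction set with a log message.
#' @return Named list of filtered candidate vectors, with attribute
#'   `n_unique_targets` (aggregated unique kept targets).
#' @export
apply_kinome_filter <- function(candidates, table, strict = FALSE) {
  stopifnot(inherits(table, "kinome_prediction_table"))
  missing <- setdiff(names(candidates), names(table$predictions))
  if (length(missing)) {
    if (strict) {
      svt_stop(paste("compound(s) missing from the kinome prediction table:",
                     paste(missing, collapse = ", ")))
    }
    svt_log(sprintf("no kinome predictions for %d compound(s); their candidates are removed",
                    length(missing)))
  }
  out <- lapply(setNames(names(candidates), names(candidates)), function(cid) {
    pred <- table$predictions[[cid]] %||% character(0)
    sort(intersect(candidates[[cid]], pred))
  })
  attr(out, "n_unique_targets") <- length(unique(unlist(out)))
  out
}
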