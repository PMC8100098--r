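#' Combine per-fingerprint SEA models by voting
#'
#' Each of the five models (one per fingerprint kind) flags a
#' (compound, target) pair when its E-value is at or below that model's
#' cutoff; the pair is predicted when at least `vote_threshold` models flag
#' it. `vote_threshold = 1` reproduces the union of the models,
#' `vote_threshold = 5` their intersection. Pairs with zero votes are
#' omitted.
#'
#' @param per_model_hits named list of hit data frames (from [sea_search()],
#'   row-bound over compounds), all computed from the same compound set and
#'   target universe. Names label the models (default `model1..k`).
#' @param e_cutoffs per-model E-value cutoffs, recycled to the number of
#'   models; the five nulls are calibrated independently so cutoffs may
#'   differ. Default `0.05`: fewer than 0.05 false targets expected per
#'   search under the extreme-value null.
#' @param vote_threshold minimum number of flagging models, in
#'   `1..length(per_model_hits)`. Default 3 (strict majority of 5).
#' @return `data.frame` of class `vote_table`: `compound_id`, `target_id`,
#'   `votes`, one `flag_<model>` column per model, `best_e_value`; restricted
#'   to `votes >= vote_threshold`, sorted by `compound_id` then ascending
#'   `best_e_value`.
#' @export
sea_vote <- function(per_model_hits, e_cutoffs = 0.05, vote_threshold = 3L) {
  n_models <- length(per_model_hits)
  if (n_models < 1L) svt_stop("at least one model's hits are required")
  if (!is.numeric(vote_threshold) || length(vote_threshold) != 1L ||
      vote_threshold < 1 || vote_threshold > n_models) {
    svt_config_error(sprintf("vote_threshold must be in 1..%d", n_models))
  }
  e_cutoffs <- rep_len(e_cutoffs, n_models)
  names(per_model_hits) <- names(per_model_hits) %||% paste0("model", seq_len(n_models))
  model_names <- names(per_model_hits)

  for (h in per_model_hits) {
    assert_cols(h, c("compound_id", "target_id", "e_value"), "hit table")
  }
  universe <- lapply(per_model_hits, function(h) sort(unique(h$target_id)))
  if (!all(vapply(universe, identical, logical(1), universe[[1]]))) {
    svt_stop("inconsistent target universes across models")
  }
  compounds <- lapply(per_model_hits, function(h) sort(unique(h$compound_id)))
  if (!all(vapply(compounds, identical, logical(1), compounds[[1]]))) {
    svt_stop("inconsistent compound sets across models")
  }

  key <- function(h) paste(h$compound_id, h$target_id, sep = "\r")
  all_pairs <- unique(do.call(rbind, lapply(per_model_hits, function(h) {
    h[, c("compound_id", "target_id")]
  })))
  pk <- key(all_pairs)
  flags <- sapply(seq_len(n_models), function(m) {
    h <- per_model_hits[[m]]
    flagged <- key(h)[h$e_value <= e_cutoffs[m]]
    as.integer(pk %in% flagged)
  })
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L)
  colnames(flags) <- paste0("flag_", model_names)

  best_e <- rep(Inf, nrow(all_pairs))
  for (h in per_model_hits) {
    idx <- match(key(h), pk)
    best_e[idx] <- pmin(best_e[idx], h$e_value)
  }

  out <- cbind(all_pairs, votes = rowSums(flags), as.data.frame(flags),
               best_e_value = best_e)
  out <- out[out$votes >= vote_threshold, , drop = FALSE]
  out <- out[order(out$compound_id, out$best_e_value, out$target_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("vote_table", "data.frame")
  out
}

#' Write a vote table as TSV
#' @param votes a `vote_table` from [sea_vote()].
#' @param path output path.
#' @export
write_vote_table <- function(votes, path) {
  utils::write.table(votes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
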