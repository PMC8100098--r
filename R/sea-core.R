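#' Similarity-ensemble (SEA) reference of target ligand sets
#'
#' A reference is a collection of per-target ligand fingerprint sets of one
#' kind/length, together with the flattened ligand pool used for background
#' calibration.
#'
#' @param sets named list of [fp_set] objects (names are target ids), or a
#'   list of lists `list(target_id =, ligands = fp_set)`.
#' @return Object of class `sea_reference`.
#' @export
sea_reference <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    svt_stop("sets must be a named list (names are target ids)")
  }
  if (anyDuplicated(names(sets))) svt_stop("target ids must be unique")
  if (length(sets) < 2L) svt_stop("a reference needs at least 2 targets")
  stopifnot(all(vapply(sets, inherits, logical(1), "fp_set")))
  kind <- sets[[1]]$kind
  for (s in sets) {
    if (s$kind != kind || s$length != sets[[1]]$length) {
      svt_stop("all target ligand sets must share fingerprint kind and length")
    }
  }
  structure(list(
    kind = kind,
    length = sets[[1]]$length,
    sets = sets,
    target_ids = names(sets),
    n_ligands = vapply(sets, length, integer(1)),
    pool = rbind_fp_sets(unname(sets))
  ), class = "sea_reference")
}

#' @export
print.sea_reference <- function(x, ...) {
  cat(sprintf("<sea_reference %s/%d: %d targets, %d pooled ligands>\n",
              x$kind, x$length, length(x$sets), length(x$pool)))
  invisible(x)
}

#' SEA raw score between two ligand sets
#'
#' Sum of all pairwise Tanimoto similarities at or above `tc_threshold`:
#' `RS(A,B) = sum Tc(a,b) * 1[Tc(a,b) >= t]` over all pairs. Zero when no
#' pair crosses the threshold.
#'
#' @param A,B [fp_set] objects of identical kind/length, both non-empty.
#' @param tc_threshold Tanimoto cutoff in (0, 1); 0.57 is the canonical SEA
#'   choice.
#' @return Non-negative scalar.
#' @export
raw_score <- function(A, B, tc_threshold = 0.57) {
  stopifnot(inherits(A, "fp_set"), inherits(B, "fp_set"))
  if (length(A) == 0L || length(B) == 0L) svt_stop("raw_score needs non-empty sets")
  tc <- tanimoto_matrix(A, B)
  sum(tc[tc >= tc_threshold])
}

#' Calibrate the SEA raw-score background
#'
#' Draws random ligand-set pairs from the reference pool at each cell of a
#' size grid, computes their raw scores, and fits the null mean and standard
#' deviation as linear functions of the set-size product
#' `n = |A| * |B|` by ordinary least squares on the per-cell statistics:
#' `mu(n) = mu_slope * n + mu_intercept`, `sigma(n) = sigma_slope * n +
#' sigma_intercept`. Reruns with the same seed reproduce identical
#' coefficients.
#'
#' @param reference a [sea_reference].
#' @param tc_threshold Tanimoto cutoff used for the raw score.
#' @param seed integer calibration seed (recorded in the model).
#' @param size_grid list of `c(sizeA, sizeB)` pairs.
#' @param reps_per_cell random set pairs per grid cell.
#' @return Object of class `sea_background` with fitted coefficients, the
#'   per-cell statistics, fit residual diagnostics and the calibration seed.
#' @export
calibrate_background <- function(reference, tc_threshold = 0.57, seed = 1L,
                                 size_grid = list(c(2, 2), c(4, 4), c(8, 8),
                                                  c(16, 16), c(32, 32)),
                                 reps_per_cell = 100L) {
  stopifnot(inherits(reference, "sea_reference"))
  pool <- reference$pool
  max_need <- max(vapply(size_grid, sum, numeric(1)))
  if (length(pool) < max_need) {
    svt_stop(sprintf(
      "ligand pool (%d) too small to sample the largest grid cell (%d) without replacement",
      length(pool), max_need))
  }
  cells <- with_seed(seed, {
    lapply(size_grid, function(sz) {
      scores <- vapply(seq_len(reps_per_cell), function(r) {
        idx <- sample.int(length(pool), sz[1] + sz[2])
        raw_score(fp_subset(pool, idx[seq_len(sz[1])]),
                  fp_subset(pool, idx[sz[1] + seq_len(sz[2])]),
                  tc_threshold)
      }, numeric(1))
      data.frame(size_a = sz[1], size_b = sz[2], n = sz[1] * sz[2],
                 mean = mean(scores), sd = stats::sd(scores),
                 se = stats::sd(scores) / sqrt(reps_per_cell))
    })
  })
  stats_df <- do.call(rbind, cells)
  if (all(stats_df$mean == 0)) {
    svt_stop(paste("degenerate background: every sampled raw score is zero;",
                   "lower tc_threshold"))
  }
  fit_mu <- stats::lm(mean ~ n, data = stats_df)
  fit_sigma <- stats::lm(sd ~ n, data = stats_df)
  model <- structure(list(
    kind = reference$kind,
    tc_threshold = tc_threshold,
    mu_slope = unname(coef(fit_mu)[2]),
    mu_intercept = unname(coef(fit_mu)[1]),
    sigma_slope = unname(coef(fit_sigma)[2]),
    sigma_intercept = unname(coef(fit_sigma)[1]),
    calib_seed = as.integer(seed),
    n_samples = as.integer(reps_per_cell) * length(size_grid),
    reps_per_cell = as.integer(reps_per_cell),
    size_grid = lapply(size_grid, as.integer),
    cell_stats = stats_df,
    mu_residuals = unname(stats::residuals(fit_mu)),
    sigma_residuals = unname(stats::residuals(fit_sigma)),
    max_n = max(stats_df$n),
    min_n = min(stats_df$n),
    extrapolation_factor = 10
  ), class = "sea_background")
  # the null must have positive spread over the calibrated range
  if (any(bg_sigma(model, stats_df$n) <= 0)) {
    svt_stop(paste("degenerate background fit: sigma(n) <= 0 over the",
                   "calibrated range (ligand pool too homogeneous?)"))
  }
  model
}

bg_mu <- function(model, n) model$mu_slope * n + model$mu_intercept
bg_sigma <- function(model, n) model$sigma_slope * n + model$sigma_intercept

#' @export
print.sea_background <- function(x, ...) {
  cat(sprintf(
    "<sea_background %s: mu(n) = %.4g n + %.4g; sigma(n) = %.4g n + %.4g; Tc >= %.2f; seed %d>\n",
    x$kind, x$mu_slope, x$mu_intercept, x$sigma_slope, x$sigma_intercept,
    x$tc_threshold, x$calib_seed))
  invisible(x)
}

#' Raw-score z-score under the calibrated background
#'
#' `z = (rs - mu(n)) / sigma(n)` with `n` the product of the two set sizes.
#' Refuses to extrapolate beyond `extrapolation_factor` (default 10) times the
#' largest calibrated `n`.
#'
#' @param rs raw score.
#' @param n set-size product.
#' @param model a `sea_background`.
#' @return z-score (vectorized over `rs`/`n`).
#' @export
zscore <- function(rs, n, model) {
  stopifnot(inherits(model, "sea_background"))
  if (any(n > model$extrapolation_factor * model$max_n)) {
    svt_stop(sprintf(
      "n = %g is beyond %gx the largest calibrated size product (%g); recalibrate with a larger grid",
      max(n), model$extrapolation_factor, model$max_n))
  }
  sig <- bg_sigma(model, n)
  if (any(sig <= 0)) svt_stop("sigma(n) <= 0 at requested n")
  (rs - bg_mu(model, n)) / sig
}

#' Extreme-value tail probability of a SEA z-score
#'
#' The null distribution of the best-matching raw score is Gumbel-type:
#' `P(z) = 1 - exp(-x)` with `x = exp(-z * pi / sqrt(6) - gamma)` and
#' `gamma` the Euler-Mascheroni constant. For `x < 1e-8` the series
#' `x - x^2/2 + x^3/6` is used to avoid catastrophic cancellation. Strictly
#' decreasing in `z`.
#'
#' @param z finite z-score (vectorized).
#' @return p-value(s) in `[0, 1]`.
#' @export
evd_pvalue <- function(z) {
  if (any(!is.finite(z))) svt_stop("z must be finite")
  gamma_em <- 0.57721566490
  x <- exp(-z * pi / sqrt(6) - gamma_em)
  small <- x < 1e-8
  p <- numeric(length(x))
  # -expm1(-x) evaluates 1 - exp(-x) without cancellation for moderate x;
  # below 1e-8 the truncated series is exact to double precision
  p[!small] <- -expm1(-x[!small])
  p[small] <- x[small] - x[small]^2 / 2 + x[small]^3 / 6
  p
}

#' Search a query ligand set against a SEA reference
#'
#' Computes one hit per reference target: raw score, z under the calibrated
#' background, extreme-value p-value, and E-value `p * n_comparisons`. Results
#' are sorted by ascending E-value, ties broken by descending best pairwise
#' Tanimoto then lexicographic target id, so output is byte-stable under any
#' reference ordering.
#'
#' @param query [fp_set] of the query compound's fingerprints (size 1 for a
#'   single compound).
#' @param reference a [sea_reference] of the same kind/length.
#' @param model a `sea_background` calibrated on this kind/threshold.
#' @param n_comparisons multiple-comparison constant; defaults to the number
#'   of targets in the reference (single-library correction).
#' @param compound_id id echoed in the output rows.
#' @return `data.frame` with columns `compound_id`, `target_id`, `raw_score`,
#'   `n`, `z`, `p_value`, `e_value`, `max_tc`.
#' @export
sea_search <- function(query, reference, model, n_comparisons = NULL,
                       compound_id = "query") {
  stopifnot(inherits(query, "fp_set"), inherits(reference, "sea_reference"),
            inherits(model, "sea_background"))
  if (query$kind != reference$kind || query$length != reference$length) {
    svt_stop("query fingerprint kind/length does not match the reference")
  }
  if (model$kind != reference$kind) {
    svt_stop("background model was calibrated for a different fingerprint kind")
  }
  n_comparisons <- n_comparisons %||% length(reference$sets)
  rows <- lapply(reference$target_ids, function(tid) {
    tset <- reference$sets[[tid]]
    tc <- tanimoto_matrix(query, tset)
    rs <- sum(tc[tc >= model$tc_threshold])
    n <- length(query) * length(tset)
    data.frame(compound_id = compound_id, target_id = tid,
               raw_score = rs, n = n, max_tc = max(tc),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits$z <- zscore(hits$raw_score, hits$n, model)
  hits$p_value <- evd_pvalue(hits$z)
  hits$e_value <- hits$p_value * n_comparisons
  hits <- hits[order(hits$e_value, -hits$max_tc, hits$target_id), ]
  rownames(hits) <- NULL
  hits[, c("compound_id", "target_id", "raw_score", "n", "z",
           "p_value", "e_value", "max_tc")]
}

#' Serialize / restore a background model as JSON
#'
#' All coefficients, the seed, the size grid and the per-cell diagnostics are
#' stored, so a model round-trips exactly.
#'
#' @param model a `sea_background`.
#' @param path JSON file path.
#' @return `write_background` returns `path` invisibly; `read_background`
#'   returns the model.
#' @export
write_background <- function(model, path) {
  stopifnot(inherits(model, "sea_background"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_background
#' @export
read_background <- function(path) {
  if (!file.exists(path)) svt_stop(paste("no such file:", path))
  obj <- jsonlite::fromJSON(path)
  obj$cell_stats <- as.data.frame(obj$cell_stats)
  obj$size_grid <- lapply(obj$size_grid, as.integer)
  structure(obj, class = "sea_background")
}

#' Read / write a SEA reference as tabular files
#'
#' The on-disk format is one ligand per row: `target_id`, `ligand_id`, and
#' either a precomputed fingerprint (`kind`, `length`, `on_bits` as a
#' semicolon-separated 0-based list) or a `smiles` column (fingerprinted on
#' load via the chemistry bridge).
#'
#' @param path TSV file.
#' @param kind,params fingerprint kind/params, used only for `smiles` input.
#' @return A [sea_reference].
#' @export
read_reference <- function(path, kind = NULL, params = fp_params()) {
  if (!file.exists(path)) svt_stop(paste("no such file:", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("target_id", "ligand_id"), "reference table")
  if ("on_bits" %in% names(df)) {
    assert_cols(df, c("kind", "length"), "reference table")
    fps <- lapply(seq_len(nrow(df)), function(i) {
      b <- if (nzchar(df$on_bits[i])) as.integer(strsplit(df$on_bits[i], ";")[[1]]) else integer(0)
      fingerprint_new(b, df$kind[i], df$length[i])
    })
  } else if ("smiles" %in% names(df)) {
    if (is.null(kind)) svt_stop("kind is required for a SMILES reference")
    fs <- fingerprint_molecules(
      data.frame(id = df$ligand_id, smiles = df$smiles, stringsAsFactors = FALSE),
      kind = kind, params = params)
    fps <- lapply(seq_len(nrow(df)), function(i) fp_at(fs, i))
  } else {
    svt_stop("reference table needs either an on_bits or a smiles column")
  }
  sets <- lapply(split(seq_len(nrow(df)), df$target_id), function(idx) {
    fp_set(fps[idx], ids = df$ligand_id[idx])
  })
  sea_reference(sets)
}

#' @rdname read_reference
#' @param reference a [sea_reference] to write.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "sea_reference"))
  rows <- lapply(reference$target_ids, function(tid) {
    s <- reference$sets[[tid]]
    data.frame(
      target_id = tid, ligand_id = s$ids, kind = s$kind, length = s$length,
      on_bits = vapply(seq_len(length(s)), function(i) {
        paste(which(s$mat[i, ] != 0) - 1L, collapse = ";")
      }, character(1)),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write SEA hits as TSV
#' @param hits data frame from [sea_search()] (possibly row-bound).
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
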