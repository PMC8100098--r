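#' Binary molecular fingerprints
#'
#' A `fingerprint` is a sparse binary feature vector: a `kind` label (one of
#' the five chemistry kinds, or an arbitrary label such as `"abstract"` for
#' synthetic bit sets), a fixed `length`, and the sorted 0-based indices of
#' the on bits. Two fingerprints are comparable only when they share kind and
#' length.
#'
#' @param bits integer vector of 0-based on-bit indices (duplicates allowed,
#'   collapsed; must all lie in `[0, length)`).
#' @param kind character scalar fingerprint kind.
#' @param length positive integer, total number of bits.
#' @return An object of class `fingerprint`.
#' @examples
#' fp <- fingerprint_new(c(1, 5, 9), "abstract", 16)
#' tanimoto(fp, fp)
#' @export
fingerprint_new <- function(bits, kind, length) {
  if (!is.character(kind) || length(kind) != 1L || !nzchar(kind)) {
    svt_stop("fingerprint kind must be a non-empty string")
  }
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) svt_stop("fingerprint length must be positive")
  bits <- sort(unique(as.integer(bits)))
  if (base::length(bits) && (min(bits) < 0L || max(bits) >= length)) {
    svt_stop("fingerprint on-bit indices must lie in [0, length)")
  }
  structure(list(kind = kind, length = length, bits = bits),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s/%d: %d bits on>\n",
              x$kind, x$length, length(x$bits)))
  invisible(x)
}

#' The five chemistry fingerprint kinds
#' @return Character vector of the supported chemistry fingerprint kinds.
#' @export
fingerprint_kinds <- function() {
  c("topological_path", "morgan", "maccs_keys", "atom_pair", "pharmacophore")
}

#' Default fingerprint parameters
#'
#' Community-default parameterizations: path fingerprint with maximum path
#' length 7 folded to 2048 bits; Morgan radius 2 folded to 2048; the 166 MACCS
#' structural keys; hashed atom pairs folded to 2048; 2-point topological
#' pharmacophore pairs folded to 2048. All overridable.
#'
#' @param ... named overrides, e.g. `morgan = list(radius = 3, n_bits = 4096)`.
#' @return Named list of per-kind parameter lists.
#' @export
fp_params <- function(...) {
  defaults <- list(
    topological_path = list(max_path = 7L, n_bits = 2048L),
    morgan           = list(radius = 2L, n_bits = 2048L),
    maccs_keys       = list(n_bits = 167L),  # rdkit convention: bit 0 unused
    atom_pair        = list(n_bits = 2048L),
    pharmacophore    = list(n_points = 2L, n_bits = 2048L)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) svt_config_error(paste("unknown fingerprint kind(s):",
                                          paste(bad, collapse = ", ")))
  for (k in names(over)) defaults[[k]] <- utils::modifyList(defaults[[k]], over[[k]])
  defaults
}

#' Tanimoto (Jaccard) similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bits. Defined as 0 when both
#' fingerprints are empty, so degenerate structures never produce spurious
#' perfect matches.
#'
#' @param a,b `fingerprint` objects of identical kind and length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  check_comparable(a, b)
  n_i <- length(intersect(a$bits, b$bits))
  n_u <- length(a$bits) + length(b$bits) - n_i
  if (n_u == 0L) return(0)
  n_i / n_u
}

check_comparable <- function(a, b) {
  if (a$kind != b$kind) {
    svt_stop(sprintf("fingerprint kind mismatch: '%s' vs '%s'", a$kind, b$kind))
  }
  if (a$length != b$length) {
    svt_stop(sprintf("fingerprint length mismatch: %d vs %d", a$length, b$length))
  }
  invisible(TRUE)
}

#' Build a fingerprint set
#'
#' An `fp_set` is an ordered collection of fingerprints of one kind/length,
#' stored as a sparse logical matrix (molecules x bits) for fast pairwise
#' similarity computation.
#'
#' @param fps list of `fingerprint` objects sharing kind and length.
#' @param ids optional character ids (defaults to names of `fps` or `fp1..n`).
#' @return An object of class `fp_set`.
#' @export
fp_set <- function(fps, ids = NULL) {
  if (inherits(fps, "fingerprint")) fps <- list(fps)
  if (!length(fps)) svt_stop("fp_set requires at least one fingerprint")
  stopifnot(all(vapply(fps, inherits, logical(1), "fingerprint")))
  kind <- fps[[1]]$kind
  len <- fps[[1]]$length
  for (f in fps) check_comparable(fps[[1]], f)
  ids <- ids %||% names(fps) %||% paste0("fp", seq_along(fps))
  i <- rep.int(seq_along(fps), vapply(fps, function(f) length(f$bits), integer(1)))
  j <- unlist(lapply(fps, `[[`, "bits"), use.names = FALSE) + 1L
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(fps), len),
                              dimnames = list(ids, NULL))
  structure(list(kind = kind, length = len, ids = ids, mat = mat),
            class = "fp_set")
}

#' @export
length.fp_set <- function(x) nrow(x$mat)

#' @export
print.fp_set <- function(x, ...) {
  cat(sprintf("<fp_set %s/%d: %d fingerprints>\n", x$kind, x$length, length(x)))
  invisible(x)
}

# subset an fp_set by row index
fp_subset <- function(x, idx) {
  structure(list(kind = x$kind, length = x$length,
                 ids = x$ids[idx], mat = x$mat[idx, , drop = FALSE]),
            class = "fp_set")
}

# extract one member as a fingerprint object
fp_at <- function(x, idx) {
  fingerprint_new(which(x$mat[idx, ] != 0) - 1L, x$kind, x$length)
}

rbind_fp_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  for (s in sets) {
    if (s$kind != sets[[1]]$kind || s$length != sets[[1]]$length) {
      svt_stop("cannot pool fp_sets of different kind/length")
    }
  }
  mat <- do.call(rbind, lapply(sets, `[[`, "mat"))
  structure(list(kind = sets[[1]]$kind, length = sets[[1]]$length,
                 ids = unlist(lapply(sets, `[[`, "ids"), use.names = FALSE),
                 mat = mat),
            class = "fp_set")
}

#' Pairwise Tanimoto matrix between two fingerprint sets
#'
#' @param A,B `fp_set` objects of identical kind and length.
#' @return Dense numeric matrix, `length(A)` x `length(B)`.
#' @export
tanimoto_matrix <- function(A, B) {
  stopifnot(inherits(A, "fp_set"), inherits(B, "fp_set"))
  check_comparable(A, B)
  inter <- as.matrix(A$mat %*% Matrix::t(B$mat))
  na <- Matrix::rowSums(A$mat)
  nb <- Matrix::rowSums(B$mat)
  uni <- outer(na, nb, `+`) - inter
  tc <- inter / uni
  tc[uni == 0] <- 0  # empty-vs-empty convention
  dimnames(tc) <- list(A$ids, B$ids)
  tc
}

#' Write / read a fingerprint cache
#'
#' Tabular, reproducible serialization: one row per fingerprint with id,
#' kind, length and the sorted on-bit list (semicolon-separated, 0-based).
#'
#' @param x `fp_set` to write.
#' @param path file path (TSV).
#' @return `write_fp_cache` returns `path` invisibly; `read_fp_cache` returns
#'   an `fp_set`.
#' @export
write_fp_cache <- function(x, path) {
  stopifnot(inherits(x, "fp_set"))
  bits <- vapply(seq_len(length(x)), function(i) {
    paste(which(x$mat[i, ] != 0) - 1L, collapse = ";")
  }, character(1))
  df <- data.frame(id = x$ids, kind = x$kind, length = x$length,
                   on_bits = bits, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fp_cache
#' @export
read_fp_cache <- function(path) {
  if (!file.exists(path)) svt_stop(paste("no such file:", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("id", "kind", "length", "on_bits"), "fingerprint cache")
  fps <- lapply(seq_len(nrow(df)), function(i) {
    b <- if (nzchar(df$on_bits[i])) as.integer(strsplit(df$on_bits[i], ";")[[1]]) else integer(0)
    fingerprint_new(b, df$kind[i], df$length[i])
  })
  fp_set(fps, ids = df$id)
}
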