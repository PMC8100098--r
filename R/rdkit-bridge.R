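# Chemistry is delegated to RDKit through a small packaged Python script;
# no R cheminformatics toolkit is assumed. Everything downstream of the
# (id, kind, length, on_bits) representation is pure R.

bridge_env <- new.env(parent = emptyenv())

svt_python <- function() {
  getOption("seavote.python", Sys.which("python"))
}

#' Is the RDKit chemistry bridge available?
#'
#' The fingerprint and SMILES-parsing operations shell out to RDKit via
#' Python. Pure bit-set workflows (synthetic references, panel screening,
#' IC50 fitting) never need it.
#'
#' @return `TRUE` if `python` with an importable `rdkit` is on the path.
#' @export
rdkit_available <- function() {
  if (!is.null(bridge_env$available)) return(bridge_env$available)
  py <- svt_python()
  ok <- nzchar(py) &&
    identical(suppressWarnings(
      system2(py, c("-c", shQuote("import rdkit")),
              stdout = FALSE, stderr = FALSE)), 0L)
  bridge_env$available <- ok
  ok
}

run_fp_bridge <- function(df, kinds = character(0), params = fp_params()) {
  if (!rdkit_available()) {
    svt_stop(paste("the RDKit chemistry bridge is unavailable (no python with",
                   "rdkit on the path); abstract fingerprints remain usable"))
  }
  script <- system.file("python", "fp_bridge.py", package = "seavote")
  if (!nzchar(script)) svt_stop("bridge script not found in installed package")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.csv(df[, c("id", "smiles")], fin, row.names = FALSE)
  status <- system2(svt_python(),
                    c(script, "--input", fin, "--output", fout,
                      if (length(kinds)) c("--kinds", paste(kinds, collapse = ",")),
                      "--params", shQuote(jsonlite::toJSON(params, auto_unbox = TRUE))),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) svt_stop("RDKit bridge failed")
  jsonlite::fromJSON(fout, simplifyVector = FALSE)$molecules
}

#' Parse compound structures from a file
#'
#' Accepts a CSV with header columns `id,smiles[,cid]` or a `.smi` file (one
#' `SMILES<whitespace>id` per line). Structures are validated and
#' canonicalized on ingest; the input spelling is preserved for provenance.
#'
#' @param path input file.
#' @param policy `"skip"` (default): invalid rows are logged and dropped;
#'   `"strict"`: the first invalid row aborts.
#' @return A data frame of class `molecule_set` with columns `id`, `smiles`
#'   (canonical), `input_smiles`, `cid`.
#' @export
parse_molecules <- function(path, policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) svt_stop(paste("no such file:", path))
  if (file.size(path) == 0) svt_stop(paste("empty input file:", path))
  df <- read_structure_file(path)
  if (!nrow(df)) svt_stop(paste("no structure records in", path))
  if (anyDuplicated(df$id)) svt_stop("molecule ids must be unique")
  if (any(!nzchar(df$id))) svt_stop("molecule ids must be non-empty")
  parsed <- run_fp_bridge(df)
  valid <- vapply(parsed, `[[`, logical(1), "valid")
  if (!all(valid)) {
    bad <- df$id[!valid]
    if (policy == "strict") {
      svt_stop(sprintf("invalid SMILES for '%s' (strict policy)", bad[1]))
    }
    svt_log(sprintf("dropped %d unparseable structure(s): %s",
                    length(bad), paste(bad, collapse = ", ")))
  }
  out <- data.frame(
    id = df$id[valid],
    smiles = vapply(parsed[valid], `[[`, character(1), "canonical_smiles"),
    input_smiles = df$smiles[valid],
    cid = if ("cid" %in% names(df)) df$cid[valid] else NA,
    stringsAsFactors = FALSE
  )
  class(out) <- c("molecule_set", "data.frame")
  out
}

read_structure_file <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    data.frame(
      id = vapply(seq_along(parts), function(i) {
        if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
      }, character(1)),
      smiles = vapply(parts, `[[`, character(1), 1),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    assert_cols(df, c("id", "smiles"), basename(path))
    df
  }
}

#' Compute fingerprints for a set of molecules
#'
#' @param mols a `molecule_set` from [parse_molecules()], or any data frame
#'   with `id` and `smiles` columns.
#' @param kind one of [fingerprint_kinds()].
#' @param params per-kind settings from [fp_params()].
#' @return An [fp_set] (one fingerprint per molecule, in input order). An
#'   empty bit set is an error for the substructure-based kinds; for
#'   `maccs_keys` (degenerate structures) and `pharmacophore` (molecules
#'   with fewer than two pharmacophoric features, e.g. plain hydrocarbons)
#'   it is legitimate and flagged via a warning.
#' @export
fingerprint_molecules <- function(mols, kind, params = fp_params()) {
  kind <- match.arg(kind, fingerprint_kinds())
  assert_cols(mols, c("id", "smiles"), "molecule table")
  parsed <- run_fp_bridge(mols, kinds = kind, params = params)
  fps <- lapply(parsed, function(m) {
    if (!isTRUE(m$valid)) svt_stop(sprintf("unparseable structure: %s", m$id))
    fp <- m$fps[[kind]]
    fingerprint_new(unlist(fp$bits), kind, fp$length)
  })
  empty <- vapply(fps, function(f) length(f$bits) == 0L, logical(1))
  if (any(empty)) {
    if (kind %in% c("maccs_keys", "pharmacophore")) {
      warning(sprintf("empty %s fingerprint for: %s", kind,
                      paste(mols$id[empty], collapse = ", ")), call. = FALSE)
    } else {
      svt_stop(sprintf("empty %s fingerprint for: %s", kind,
                       paste(mols$id[empty], collapse = ", ")))
    }
  }
  fp_set(fps, ids = mols$id)
}

#' Fingerprint a single SMILES string
#'
#' @param smiles a single SMILES string.
#' @inheritParams fingerprint_molecules
#' @return A `fingerprint` object.
#' @export
fingerprint_smiles <- function(smiles, kind, params = fp_params()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  fs <- fingerprint_molecules(
    data.frame(id = "query", smiles = smiles, stringsAsFactors = FALSE),
    kind = kind, params = params)
  fp_at(fs, 1L)
}
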