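# in-code fixtures: abstract fingerprints, tiny references, and small
# molecule tables; everything is generated, nothing binary is stored

options(seavote.quiet = TRUE)

afp <- function(bits, len = 64L, kind = "abstract") {
  fingerprint_new(bits, kind, len)
}

# random fp_set with n_on bits per fingerprint
random_fp_set <- function(n, len = 256L, n_on = 24L, seed = 1L,
                          kind = "abstract") {
  set.seed(seed)
  fp_set(lapply(seq_len(n), function(i) {
    fingerprint_new(sample.int(len, n_on) - 1L, kind, len)
  }))
}

# brute-force oracles, deliberately independent of the Matrix-based path
tanimoto_pair_oracle <- function(a, b) {
  ni <- length(intersect(a, b))
  nu <- length(union(a, b))
  if (nu == 0) 0 else ni / nu
}

raw_score_oracle <- function(A, B, thr) {
  # every pairwise Tc recomputed from plain set algebra; qualifying values
  # accumulated in column-major order so the summation order matches sum()
  # over a matrix mask and equality can be exact
  vals <- c()
  for (j in seq_len(length(B))) {
    for (i in seq_len(length(A))) {
      tc <- tanimoto_pair_oracle(which(A$mat[i, ] != 0), which(B$mat[j, ] != 0))
      if (tc >= thr) vals <- c(vals, tc)
    }
  }
  if (is.null(vals)) 0 else sum(vals)
}

# small planted reference: 4 targets x 5 ligands, crisp chemotypes; the
# 20-ligand pool needs a correspondingly small calibration grid
tiny_world <- function(seed = 42L) {
  generate_reference(synthetic_spec(seed = seed, n_targets = 4L,
                                    ligands_per_target = 5L,
                                    chemotype_similarity = 0.75,
                                    background_similarity = 0.02,
                                    fp_length = 512L, bits_per_ligand = 32L,
                                    queries_per_target = 2L))
}

tiny_grid <- list(c(2L, 2L), c(3L, 3L), c(4L, 4L), c(5L, 5L))

calibrate_tiny <- function(reference, seed) {
  calibrate_background(reference, seed = seed, size_grid = tiny_grid,
                       reps_per_cell = 150L)
}

# memoize full prediction runs shared across test files
.pred_cache <- new.env(parent = emptyenv())
cached_predict <- function(seed) {
  key <- as.character(seed)
  if (is.null(.pred_cache[[key]])) {
    .pred_cache[[key]] <- run_predict(default_config(seed = seed))
  }
  .pred_cache[[key]]
}

write_tmp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

table3_path <- function() {
  system.file("extdata", "table3_panel_25ug.csv", package = "seavote")
}
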