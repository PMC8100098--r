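test_that("tanimoto matches its set-algebra definition on worked cases", {
  expect_equal(tanimoto(afp(c(1, 2, 3)), afp(c(1, 2, 3))), 1.0)
  expect_equal(tanimoto(afp(c(1, 2)), afp(c(5, 6))), 0.0)
  expect_equal(tanimoto(afp(c(1, 2, 3)), afp(c(2, 3, 4))), 0.5)
  # both-empty convention: 0, not NaN
  expect_identical(tanimoto(afp(integer(0)), afp(integer(0))), 0)
})

test_that("tanimoto is symmetric and reflexive over random bit sets", {
  set.seed(101)
  for (i in 1:50) {
    a <- afp(sample.int(64, sample(1:20, 1)) - 1L)
    b <- afp(sample.int(64, sample(1:20, 1)) - 1L)
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto(a, b),
                 tanimoto_pair_oracle(a$bits, b$bits))
    expect_equal(tanimoto(a, a), 1.0)
  }
})

test_that("incomparable fingerprints are rejected", {
  expect_error(tanimoto(afp(1:3), afp(1:3, kind = "other")), "kind mismatch")
  expect_error(tanimoto(afp(1:3, len = 64), afp(1:3, len = 128)),
               "length mismatch")
  expect_error(fingerprint_new(c(-1, 5), "abstract", 64), "indices")
  expect_error(fingerprint_new(64, "abstract", 64), "indices")
})

test_that("tanimoto_matrix agrees with pairwise tanimoto", {
  A <- random_fp_set(4, seed = 7)
  B <- random_fp_set(6, seed = 8)
  m <- tanimoto_matrix(A, B)
  for (i in 1:4) for (j in 1:6) {
    expect_equal(m[i, j], tanimoto(seavote:::fp_at(A, i), seavote:::fp_at(B, j)))
  }
})

test_that("fingerprint cache round-trips exactly", {
  A <- random_fp_set(5, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_fp_cache(A, path)
  B <- read_fp_cache(path)
  expect_identical(B$ids, A$ids)
  expect_equal(as.matrix(B$mat), as.matrix(A$mat), ignore_attr = TRUE)
  expect_identical(B$kind, A$kind)
})

# ---- chemistry bridge -------------------------------------------------------

test_that("parse_molecules handles valid, invalid and policy variants", {
  one <- write_tmp_csv(data.frame(id = "benzene", smiles = "c1ccccc1"))
  mols <- parse_molecules(one)
  expect_equal(nrow(mols), 1L)
  expect_identical(mols$id, "benzene")

  mixed <- write_tmp_csv(data.frame(
    id = c("ok1", "broken", "ok2"),
    smiles = c("CCO", "C1CC", "c1ccccc1O")))
  kept <- parse_molecules(mixed, policy = "skip")
  expect_equal(nrow(kept), 2L)
  expect_identical(kept$id, c("ok1", "ok2"))
  expect_error(parse_molecules(mixed, policy = "strict"),
               "invalid SMILES.*broken")

  expect_error(parse_molecules(tempfile()), "no such file")
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(parse_molecules(empty), "empty")
})

test_that("a 40-row component table parses into 40 molecules", {
  # mirrors the packaged 40-component input set; the printed table carries
  # ids + database CIDs, structures here are small stand-ins
  comp <- utils::read.csv(system.file("extdata", "table1_components.csv",
                                      package = "seavote"))
  expect_equal(nrow(comp), 40L)
  df <- data.frame(id = comp$id,
                   smiles = rep(c("CCO", "c1ccccc1", "CC(=O)O", "C1CCCCC1"),
                                10))
  mols <- parse_molecules(write_tmp_csv(df))
  expect_equal(nrow(mols), 40L)
})

test_that(".smi input is accepted", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CCO ethanol"), path)
  mols <- parse_molecules(path)
  expect_identical(mols$id, c("benzene", "ethanol"))
})

test_that("benzene MACCS keys match the independent reference key set", {
  # aromatic (162), six-membered ring (163), ring (165)
  fp <- fingerprint_smiles("c1ccccc1", "maccs_keys")
  expect_identical(fp$bits, c(162L, 163L, 165L))
})

test_that("fingerprints are deterministic and canonicalization-insensitive", {
  reps <- data.frame(id = sprintf("r%03d", 1:100),
                     smiles = rep("CC(=O)Oc1ccccc1C(=O)O", 100))
  for (kind in c("morgan", "topological_path")) {
    fs <- fingerprint_molecules(reps, kind)
    bits <- lapply(seq_len(100), function(i) which(fs$mat[i, ] != 0))
    expect_true(all(vapply(bits, identical, logical(1), bits[[1]])))
  }
  # two spellings of the same molecule (salicylic acid, which carries
  # pharmacophoric features for every kind)
  spellings <- data.frame(id = c("a", "b"),
                          smiles = c("O=C(O)c1ccccc1O", "OC(=O)c1ccccc1O"))
  for (kind in fingerprint_kinds()) {
    fs <- fingerprint_molecules(spellings, kind)
    expect_identical(which(fs$mat[1, ] != 0), which(fs$mat[2, ] != 0),
                     label = kind)
    expect_gt(length(which(fs$mat[1, ] != 0)), 0)
  }
})

test_that("feature-free molecules give flagged empty pharmacophore prints", {
  expect_warning(
    fp <- fingerprint_molecules(data.frame(id = "benzene",
                                           smiles = "c1ccccc1"),
                                "pharmacophore"),
    "empty pharmacophore")
  expect_equal(length(seavote:::fp_at(fp, 1)$bits), 0L)
})

test_that("distinct structures give distinct morgan fingerprints", {
  fs <- fingerprint_molecules(
    data.frame(id = c("methane", "benzene"), smiles = c("C", "c1ccccc1")),
    "morgan")
  expect_false(identical(which(fs$mat[1, ] != 0), which(fs$mat[2, ] != 0)))
})

test_that("fingerprint parameters control the output space", {
  fp1 <- fingerprint_smiles("c1ccccc1O", "morgan")
  expect_equal(fp1$length, 2048L)
  fp2 <- fingerprint_smiles("c1ccccc1O", "morgan",
                            params = fp_params(morgan = list(n_bits = 1024L)))
  expect_equal(fp2$length, 1024L)
  expect_error(fp_params(bogus = list(n_bits = 10)), "unknown fingerprint kind")
})
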