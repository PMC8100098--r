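test_that("the planted reference hits its similarity design (seed 7)", {
  w <- generate_reference(synthetic_spec(seed = 7))
  r <- w$reference
  expect_equal(length(r$sets), 20L)
  expect_equal(unname(r$n_ligands), rep(10L, 20))
  within <- unlist(lapply(r$sets, function(s) {
    m <- tanimoto_matrix(s, s); m[upper.tri(m)]
  }))
  between <- unlist(lapply(1:5, function(i) {
    as.vector(tanimoto_matrix(r$sets[[i]], r$sets[[i + 5]]))
  }))
  expect_lt(abs(mean(within) - 0.7), 0.05)
  expect_lt(abs(mean(between) - 0.05), 0.05)
  expect_equal(nrow(w$truth), 60L)  # 3 planted queries per target
})

test_that("degenerate similarity settings produce the forced geometries", {
  # chemotype similarity 1: all ligands of a target identical
  w1 <- generate_reference(synthetic_spec(seed = 1, n_targets = 3,
                                          ligands_per_target = 4,
                                          chemotype_similarity = 1,
                                          background_similarity = 0.01,
                                          fp_length = 512, bits_per_ligand = 16,
                                          queries_per_target = 0))
  for (s in w1$reference$sets) {
    m <- tanimoto_matrix(s, s)
    expect_true(all(m == 1))
  }
  # background similarity 0 with disjoint allocation: cross-target Tc exactly 0
  w0 <- generate_reference(synthetic_spec(seed = 2, n_targets = 3,
                                          ligands_per_target = 4,
                                          chemotype_similarity = 0.6,
                                          background_similarity = 0,
                                          fp_length = 1024, bits_per_ligand = 16,
                                          queries_per_target = 1))
  expect_true(all(tanimoto_matrix(w0$reference$sets[[1]],
                                  w0$reference$sets[[2]]) == 0))
  # infeasible: bits cannot fit in the fingerprint
  expect_error(generate_reference(synthetic_spec(seed = 3, n_targets = 50,
                                                 chemotype_similarity = 0.9,
                                                 background_similarity = 0.01,
                                                 fp_length = 256,
                                                 bits_per_ligand = 64)),
               "infeasible")
  expect_error(synthetic_spec(chemotype_similarity = 0.1,
                              background_similarity = 0.5),
               "must exceed")
})

test_that("generators are pure functions of the seed", {
  a <- generate_reference(synthetic_spec(seed = 7))
  b <- generate_reference(synthetic_spec(seed = 7))
  expect_equal(as.matrix(a$reference$pool$mat), as.matrix(b$reference$pool$mat),
               ignore_attr = TRUE)
  expect_identical(a$truth, b$truth)
  c_ <- generate_reference(synthetic_spec(seed = 8))
  expect_false(identical(as.matrix(a$reference$pool$mat),
                         as.matrix(c_$reference$pool$mat)))
  p1 <- generate_panel(c("KIN001", "KIN002"), 10, seed = 5)
  p2 <- generate_panel(c("KIN001", "KIN002"), 10, seed = 5)
  expect_identical(p1, p2)
  d1 <- generate_dose_response(1, seed = 23)
  d2 <- generate_dose_response(1, seed = 23)
  expect_identical(d1$responses, d2$responses)
})

test_that("panel generator places activities where the design says", {
  actives <- sprintf("KIN%03d", 1:30)
  exact <- generate_panel(actives, 100, active_mean = 50, inactive_mean = 95,
                          noise_sd = 0, seed = 3)
  expect_true(all(exact$activity_pct[exact$gene_symbol %in% actives] == 50))
  expect_true(all(exact$activity_pct[!exact$gene_symbol %in% actives] == 95))
  # stated design: 100 kinases, 30 true actives at 50 vs 95, SD 5 -> the 80%
  # screen recovers nearly all planted actives (6-sigma separation)
  noisy <- generate_panel(actives, 100, active_mean = 50, inactive_mean = 95,
                          noise_sd = 5, seed = 3)
  called <- screen_active(noisy, 80)$gene_symbol
  expect_gte(sum(actives %in% called), 28)
  expect_error(generate_panel("NOT_THERE", 5, seed = 1), "subset")
})

test_that("dose-response generator lies on the curve at zero noise", {
  s0 <- generate_dose_response(ic50 = 2, hill = 1.5, top = 100, bottom = 5,
                               series = make_dilution_series(50, 8),
                               noise_sd = 0, n_replicates = 2, seed = 1)
  mu <- seavote:::logistic4(s0$concentrations, 5, 100, 2, 1.5)
  expect_equal(s0$responses[1, ], mu)
  expect_equal(s0$responses[2, ], mu)
  const <- generate_dose_response(ic50 = 2, top = 70, bottom = 70,
                                  noise_sd = 0, n_replicates = 1, seed = 1)
  expect_true(all(const$responses == 70))
  expect_identical(attr(s0, "truth")$ic50, 2)
})

test_that("packaged fixture tables have the printed shapes", {
  fx <- load_paper_fixtures()
  expect_equal(nrow(fx$components), 40L)
  expect_equal(nrow(fx$panel_25), 30L)
  expect_equal(nrow(fx$dose_pairs), 14L)
  expect_equal(nrow(fx$ic50), 4L)
  expect_identical(fx$ic50$target_id, c("AURKB", "MET", "PIM1", "SYK"))
  # the one typographically ambiguous high-dose value is missing, not guessed
  expect_true(is.na(fx$dose_pairs$activity_250ug[fx$dose_pairs$gene_symbol == "CLK1"]))
  expect_equal(sum(is.na(fx$dose_pairs$activity_250ug)), 1L)
  # the 30 panel kinases are all in the shipped vocabulary
  expect_true(all(fx$panel_25$gene_symbol %in% fx$kinase_vocabulary$gene_symbol))
  # internal consistency: retest rows are the panel rows below 70
  expect_setequal(fx$dose_pairs$gene_symbol,
                  fx$panel_25$gene_symbol[fx$panel_25$activity_pct < 70])
  expect_equal(fx$dose_pairs$activity_25ug,
               fx$panel_25$activity_pct[match(fx$dose_pairs$gene_symbol,
                                              fx$panel_25$gene_symbol)])
})
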