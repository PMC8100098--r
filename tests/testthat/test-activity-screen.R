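test_that("the packaged 25 ug/mL panel reads and validates", {
  panel <- read_panel(table3_path())
  expect_equal(nrow(panel), 30L)
  expect_true(all(panel$concentration == 25))
  expect_true(all(panel$activity_pct >= 0 & panel$activity_pct <= 100))
  # malformed inputs
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(read_panel(empty), "empty")
  neg <- panel; neg$activity_pct[3] <- -5
  expect_error(seavote:::validate_panel(neg), "negative")
  dup <- rbind(panel, panel[1, ])
  expect_error(seavote:::validate_panel(dup), "duplicate")
})

test_that("active calls at the 80% threshold are inclusive", {
  panel <- read_panel(table3_path())
  actives <- screen_active(panel, threshold = 80, inclusive = TRUE)
  expect_equal(nrow(actives), 30L)  # every printed row is a called active
  # the two kinases sitting exactly at the threshold stay in
  expect_true(all(c("DYRK1A", "IRAK4") %in% actives$gene_symbol))
  expect_false(is.unsorted(actives$activity_pct))
  # the exclusive variant drops exactly those boundary rows
  excl <- screen_active(panel, threshold = 80, inclusive = FALSE)
  expect_equal(nrow(excl), 28L)
  expect_false(any(c("DYRK1A", "IRAK4") %in% excl$gene_symbol))
  # no inhibition anywhere: empty call set
  flat <- panel; flat$activity_pct <- 100
  expect_equal(nrow(screen_active(flat, 80)), 0L)
  mixed <- panel; mixed$concentration[1] <- 250
  expect_error(screen_active(mixed), "single concentration")
})

test_that("retest selection is strictly below 70", {
  panel <- read_panel(table3_path())
  actives <- screen_active(panel)
  retest <- select_retest(actives, cutoff = 70, strict = TRUE)
  expect_equal(nrow(retest), 14L)
  expect_true(all(retest$activity_pct < 70))
  # boundary: a kinase at exactly 70 is excluded under the strict rule
  boundary <- actives; boundary$activity_pct[1] <- 70
  expect_false(boundary$gene_symbol[1] %in%
                 select_retest(boundary, 70, strict = TRUE)$gene_symbol)
  expect_true(boundary$gene_symbol[1] %in%
                select_retest(boundary, 70, strict = FALSE)$gene_symbol)
  expect_equal(nrow(select_retest(actives[0, ])), 0L)
})

test_that("dose-dependence flags reproduce the printed retest outcome", {
  pairs <- load_paper_fixtures()$dose_pairs
  low <- data.frame(gene_symbol = pairs$gene_symbol,
                    activity_pct = pairs$activity_25ug)
  high <- data.frame(gene_symbol = pairs$gene_symbol,
                     activity_pct = pairs$activity_250ug)
  flags <- flag_dose_dependent(low, high, margin = 10)
  # the nine flagged kinases, exactly as printed
  expect_identical(
    sort(flags$gene_symbol[which(flags$dose_dependent)]),
    c("AURKB", "CSNK1G3", "CSNK2A1", "CSNK2A2", "FGFR1", "GSK3B", "MET",
      "PIM1", "SYK"))
  # worked rows: CSNK2A1 65 -> 47 flagged; RET 61 -> 70 (rebound) not flagged
  expect_true(flags$dose_dependent[flags$gene_symbol == "CSNK2A1"])
  expect_false(flags$dose_dependent[flags$gene_symbol == "RET"])
  # CLK1's ambiguous high-dose value propagates as NA, never a guess
  expect_true(is.na(flags$dose_dependent[flags$gene_symbol == "CLK1"]))
  # identical activities at both doses: no flag at any positive margin
  same <- data.frame(gene_symbol = "X", activity_pct = 50)
  expect_false(flag_dose_dependent(same, same, margin = 10)$dose_dependent)
  expect_false(flag_dose_dependent(same, same, margin = 0)$dose_dependent)
})

test_that("dose flags are anti-monotone in the margin", {
  pairs <- load_paper_fixtures()$dose_pairs
  ok <- !is.na(pairs$activity_250ug)
  low <- data.frame(gene_symbol = pairs$gene_symbol[ok],
                    activity_pct = pairs$activity_25ug[ok])
  high <- data.frame(gene_symbol = pairs$gene_symbol[ok],
                     activity_pct = pairs$activity_250ug[ok])
  counts <- vapply(c(0, 5, 10, 20, 40), function(m) {
    sum(flag_dose_dependent(low, high, margin = m)$dose_dependent)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # margin 0 flags every strict decrease (and SYK's 63 -> 2 among them)
  expect_equal(counts[1], sum(high$activity_pct < low$activity_pct))
  expect_error(flag_dose_dependent(low, high[-1, , drop = FALSE]), "missing")
})

test_that("screen stages nest: retest within actives within panel", {
  for (seed in c(3, 4)) {
    panel <- generate_panel(sprintf("KIN%03d", 1:25), 80, seed = seed)
    res <- run_screen(panel)
    expect_true(all(res$retest$gene_symbol %in% res$actives$gene_symbol))
    expect_true(all(res$actives$gene_symbol %in% panel$gene_symbol))
    # threshold 100 keeps everything at-or-below blank; threshold 0 keeps
    # only complete inhibition
    expect_equal(nrow(screen_active(panel, 100)),
                 sum(panel$activity_pct <= 100))
    expect_equal(nrow(screen_active(panel, 0)),
                 sum(panel$activity_pct == 0))
  }
  expect_error(run_screen(generate_panel(character(0), 5, seed = 1),
                          active_threshold = 60, retest_cutoff = 70),
               "retest cutoff")
})
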