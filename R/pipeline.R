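#' Default pipeline configuration
#'
#' One nested list drives every stage; unknown keys are rejected by
#' [validate_config()] and the full configuration is serialized verbatim
#' into every run manifest. `mode` selects where inputs come from:
#' `"synthetic"` (planted-structure generators; the default, fully offline),
#' `"paper_fixtures"` (the packaged printed tables) or `"files"` (paths in
#' `$inputs`).
#'
#' @param seed master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    mode = "synthetic",
    synthetic = list(n_targets = 20L, ligands_per_target = 10L,
                     chemotype_similarity = 0.7, background_similarity = 0.05,
                     fp_length = 2048L, bits_per_ligand = 64L,
                     queries_per_target = 3L,
                     known_fraction = 0.5, active_fraction = 0.3,
                     panel_noise_sd = 5, ic50_targets = 2L,
                     ic50_true = 1.0, ic50_hill = 1, ic50_noise_sd = 3,
                     ic50_replicates = 3L),
    sea = list(n_models = 5L, tc_threshold = 0.57,
               size_grid = list(c(2L, 2L), c(4L, 4L), c(8L, 8L),
                                c(16L, 16L), c(32L, 32L)),
               reps_per_cell = 100L),
    vote = list(e_cutoffs = 0.05, vote_threshold = 3L),
    kinome = list(source = "surrogate", tc_cutoff = 0.57,
                  table_path = NULL, vocabulary_path = NULL),
    screen = list(active_threshold = 80, inclusive = TRUE,
                  retest_cutoff = 70, strict = TRUE, dose_margin = 10),
    ic50 = list(flat_tol = 10),
    inputs = list(reference_paths = NULL, query_paths = NULL,
                  known_targets_path = NULL, panel_path = NULL,
                  high_panel_path = NULL, dose_response_path = NULL)
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys (against the [default_config()] skeleton) and
#' internally contradictory settings.
#'
#' @param config configuration list (possibly partial; missing keys take
#'   defaults).
#' @return The completed, validated configuration, invisibly usable.
#' @export
validate_config <- function(config) {
  def <- default_config(config$seed %||% 1L)
  check_keys <- function(x, ref, path) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown)) {
      svt_config_error(paste0("unknown configuration key(s): ",
                              paste(paste0(path, unknown), collapse = ", ")))
    }
  }
  check_keys(config, def, "")
  for (sec in c("synthetic", "sea", "vote", "kinome", "screen", "ic50", "inputs")) {
    if (!is.null(config[[sec]])) {
      if (!is.list(config[[sec]])) svt_config_error(paste(sec, "must be a list"))
      check_keys(config[[sec]], def[[sec]], paste0(sec, "$"))
      # wholesale per-key replacement: list-valued settings (size_grid,
      # e_cutoffs, paths) override rather than merge element-wise
      for (k in names(config[[sec]])) def[[sec]][[k]] <- config[[sec]][[k]]
    }
  }
  for (k in setdiff(names(config), c("synthetic", "sea", "vote", "kinome",
                                     "screen", "ic50", "inputs"))) {
    def[[k]] <- config[[k]]
  }
  cfg <- def
  # canonical form: unset (NULL) keys are dropped so that validation is
  # idempotent and manifests round-trip byte-identically
  drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]
  for (sec in c("synthetic", "sea", "vote", "kinome", "screen", "ic50",
                "inputs")) {
    cfg[[sec]] <- drop_nulls(cfg[[sec]])
  }
  cfg <- drop_nulls(cfg)
  if (!cfg$mode %in% c("synthetic", "paper_fixtures", "files")) {
    svt_config_error("mode must be one of synthetic, paper_fixtures, files")
  }
  if (cfg$vote$vote_threshold < 1 || cfg$vote$vote_threshold > cfg$sea$n_models) {
    svt_config_error(sprintf("vote_threshold must be in 1..%d", cfg$sea$n_models))
  }
  if (cfg$sea$tc_threshold <= 0 || cfg$sea$tc_threshold >= 1) {
    svt_config_error("tc_threshold must be in (0, 1)")
  }
  if (cfg$screen$retest_cutoff > cfg$screen$active_threshold) {
    svt_config_error("retest cutoff cannot exceed the active threshold")
  }
  cfg
}

#' Read a configuration from JSON
#' @param path JSON file of configuration overrides.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) svt_config_error(paste("no such config file:", path))
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!is.null(cfg$sea$size_grid)) {
    cfg$sea$size_grid <- lapply(cfg$sea$size_grid, as.integer)
  }
  validate_config(cfg)
}

# build the five per-model (reference, queries) worlds
build_model_worlds <- function(cfg) {
  stage <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      svt_stop(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  if (cfg$mode == "files") {
    paths <- cfg$inputs$reference_paths
    qpaths <- cfg$inputs$query_paths
    if (is.null(paths) || is.null(qpaths)) {
      svt_config_error("files mode requires inputs$reference_paths and inputs$query_paths")
    }
    worlds <- lapply(seq_along(paths), function(m) {
      ref <- stage(read_reference(paths[[m]]), "reference")
      qset <- stage(read_fp_cache(qpaths[[m]]), "queries")
      queries <- lapply(seq_len(length(qset)), function(i) fp_subset(qset, i))
      names(queries) <- qset$ids
      list(reference = ref, queries = queries, truth = NULL)
    })
    names(worlds) <- names(paths) %||% paste0("model", seq_along(paths))
    return(worlds)
  }
  worlds <- lapply(seq_len(cfg$sea$n_models), function(m) {
    sp <- synthetic_spec(
      seed = derive_seed(cfg$seed, m),
      n_targets = cfg$synthetic$n_targets,
      ligands_per_target = cfg$synthetic$ligands_per_target,
      chemotype_similarity = cfg$synthetic$chemotype_similarity,
      background_similarity = cfg$synthetic$background_similarity,
      kind = paste0("model", m),
      fp_length = cfg$synthetic$fp_length,
      bits_per_ligand = cfg$synthetic$bits_per_ligand,
      queries_per_target = cfg$synthetic$queries_per_target)
    generate_reference(sp)
  })
  names(worlds) <- paste0("model", seq_len(cfg$sea$n_models))
  worlds
}

#' Run the prediction stage: five SEA models plus voting
#'
#' Calibrates a background per model, searches every query compound against
#' that model's reference, and combines the per-model hit lists by voting.
#' With an output directory, per-model hit TSVs, the vote table and a JSON
#' manifest (configuration, derived seeds, package version) are written;
#' reruns with identical configuration are byte-identical.
#'
#' @param config configuration list (see [default_config()]); validated
#'   internally.
#' @param out_dir optional output directory.
#' @return list: `hits` (named list of per-model hit tables), `vote_table`,
#'   `models` (calibrated backgrounds), `truth` (planted associations, when
#'   synthetic), `manifest`.
#' @export
run_predict <- function(config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  worlds <- build_model_worlds(cfg)
  calib_seeds <- vapply(seq_along(worlds), function(m) derive_seed(cfg$seed, 100L + m),
                        integer(1))
  models <- list()
  hits <- list()
  for (m in seq_along(worlds)) {
    w <- worlds[[m]]
    model <- tryCatch(
      calibrate_background(w$reference, tc_threshold = cfg$sea$tc_threshold,
                           seed = calib_seeds[m],
                           size_grid = cfg$sea$size_grid,
                           reps_per_cell = cfg$sea$reps_per_cell),
      error = function(e) svt_stop(sprintf("[stage calibrate/%s] %s",
                                           names(worlds)[m], conditionMessage(e))))
    h <- do.call(rbind, lapply(names(w$queries), function(cid) {
      sea_search(w$queries[[cid]], w$reference, model, compound_id = cid)
    }))
    models[[names(worlds)[m]]] <- model
    hits[[names(worlds)[m]]] <- h
  }
  votes <- sea_vote(hits, e_cutoffs = cfg$vote$e_cutoffs,
                    vote_threshold = cfg$vote$vote_threshold)
  manifest <- list(package = "seavote",
                   version = as.character(utils::packageVersion("seavote")),
                   config = cfg, calib_seeds = calib_seeds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in names(hits)) {
      write_hits(hits[[m]], file.path(out_dir, paste0("hits_", m, ".tsv")))
    }
    write_vote_table(votes, file.path(out_dir, "vote_table.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(hits = hits, vote_table = votes, models = models,
       truth = worlds[[1]]$truth, worlds = worlds, manifest = manifest)
}

#' Run the full pipeline: predict, filter, integrate, screen, fit
#'
#' In `synthetic` mode the voted predictions are filtered through the
#' similarity surrogate of the kinome stage, merged with a seeded "known"
#' annotation subset of the planted truth, counted by provenance, screened
#' on a generated panel, and two dose-response series are fitted. In
#' `paper_fixtures` mode the packaged printed tables are the inputs: the
#' partition counts, panel screen and accuracy summary are recomputed from
#' them. Every output is accompanied by a manifest.
#'
#' @inheritParams run_predict
#' @return list with stage outputs: `partition` (data frame of partition
#'   counts), `screen` (a `screen_result`), `accuracy`, `ic50`, plus
#'   prediction-stage outputs in synthetic mode, and `manifest`.
#' @export
run_full <- function(config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  out <- if (cfg$mode == "paper_fixtures") run_full_fixtures(cfg)
         else run_full_synthetic(cfg)
  out$manifest <- list(package = "seavote",
                       version = as.character(utils::packageVersion("seavote")),
                       config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$partition, file.path(out_dir, "partition_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$accuracy, file.path(out_dir, "accuracy_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$screen$actives, file.path(out_dir, "screen_actives.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$screen$dose_flags)) {
      utils::write.table(out$screen$dose_flags, file.path(out_dir, "dose_flags.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(out$ic50)) {
      utils::write.table(out$ic50, file.path(out_dir, "ic50_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

run_full_fixtures <- function(cfg) {
  fx <- load_paper_fixtures()
  t2 <- fx$partition_counts
  row_of <- function(src, col) t2[[col]][t2$target_source == src]
  partition <- do.call(rbind, lapply(
    c(all_targets = "all_targets", kinase_targets = "kinase_targets",
      kinomex_screened = "kinomex_screened"),
    function(col) {
      rec <- records_from_counts(row_of("known", col), row_of("predicted", col),
                                 row_of("common", col))
      cbind(column = col, partition_counts(rec))
    }))
  rownames(partition) <- NULL

  # reconstruct the screened record set and its panel outcome from the
  # printed per-provenance counts, then recompute the accuracies
  t4 <- fx$accuracy
  a_of <- function(src, col) t4[[col]][t4$target_source == src]
  rec <- records_from_counts(a_of("known", "kinomex_screened"),
                             a_of("predicted", "kinomex_screened"),
                             a_of("common", "kinomex_screened"))
  ids <- function(p) rec$target_id[rec$provenance == p]
  n_tested_predonly <- a_of("predicted", "in_full_kp_panel") -
    a_of("common", "in_full_kp_panel")
  tested <- c(ids("known"), ids("common"),
              ids("predicted")[seq_len(n_tested_predonly)])
  n_active_common <- a_of("common", "active_targets")
  n_active_knownonly <- a_of("known", "active_targets") - n_active_common
  n_active_predonly <- a_of("predicted", "active_targets") - n_active_common
  active <- c(ids("known")[seq_len(n_active_knownonly)],
              ids("predicted")[seq_len(n_active_predonly)],
              ids("common")[seq_len(n_active_common)])
  accuracy <- accuracy_summary(rec, tested, active)

  high <- fx$dose_pairs
  high_panel <- data.frame(gene_symbol = high$gene_symbol,
                           activity_pct = high$activity_250ug,
                           stringsAsFactors = FALSE)
  screen <- run_screen(fx$panel_25, high_panel = high_panel,
                       active_threshold = cfg$screen$active_threshold,
                       inclusive = cfg$screen$inclusive,
                       retest_cutoff = cfg$screen$retest_cutoff,
                       strict = cfg$screen$strict,
                       dose_margin = cfg$screen$dose_margin)
  list(partition = partition, accuracy = accuracy, screen = screen,
       ic50 = fx$ic50, records = rec)
}

run_full_synthetic <- function(cfg) {
  pred <- run_predict(cfg)
  votes <- pred$vote_table
  candidates <- split(votes$target_id, votes$compound_id)

  # kinome stage: similarity surrogate against the first model's reference
  # (in the synthetic world every target is a kinase)
  ktab <- surrogate_predict_table(pred$worlds[[1]]$queries,
                                  pred$worlds[[1]]$reference,
                                  tc_cutoff = cfg$kinome$tc_cutoff)
  filtered <- apply_kinome_filter(candidates, ktab)

  # seeded "database" annotations: a fraction of the planted truth is known
  truth <- pred$truth
  known_idx <- with_seed(derive_seed(cfg$seed, 201L), {
    sort(sample.int(nrow(truth), round(cfg$synthetic$known_fraction * nrow(truth))))
  })
  known <- data.frame(target_name = truth$target_id[known_idx],
                      compound_id = truth$compound_id[known_idx],
                      stringsAsFactors = FALSE)
  predicted <- data.frame(
    target_name = unlist(filtered, use.names = FALSE),
    compound_id = rep(names(filtered), lengths(filtered)),
    stringsAsFactors = FALSE)
  records <- integrate_targets(known, predicted)
  records$is_kinase <- TRUE
  partition <- partition_counts(records)

  # panel: every integrated target is assayed; a seeded subset is genuinely
  # inhibited
  kin <- sort(records$target_id)
  n_active <- max(1L, round(cfg$synthetic$active_fraction * length(kin)))
  true_actives <- with_seed(derive_seed(cfg$seed, 202L), {
    sort(sample(kin, n_active))
  })
  panel <- generate_panel(true_actives, n_kinases = length(kin),
                          noise_sd = cfg$synthetic$panel_noise_sd,
                          seed = derive_seed(cfg$seed, 203L), kinases = kin)
  high_panel <- generate_panel(true_actives, n_kinases = length(kin),
                               active_mean = 25, inactive_mean = 95,
                               noise_sd = cfg$synthetic$panel_noise_sd,
                               seed = derive_seed(cfg$seed, 204L),
                               kinases = kin, concentration = 250)
  screen <- run_screen(panel, high_panel = high_panel,
                       active_threshold = cfg$screen$active_threshold,
                       inclusive = cfg$screen$inclusive,
                       retest_cutoff = cfg$screen$retest_cutoff,
                       strict = cfg$screen$strict,
                       dose_margin = cfg$screen$dose_margin)
  accuracy <- accuracy_summary(records, tested = kin,
                               active = screen$actives$gene_symbol)

  fits <- lapply(seq_len(min(cfg$synthetic$ic50_targets, length(kin))), function(i) {
    series <- generate_dose_response(
      ic50 = cfg$synthetic$ic50_true, hill = cfg$synthetic$ic50_hill,
      series = make_dilution_series(cfg$synthetic$ic50_true * 81),
      noise_sd = cfg$synthetic$ic50_noise_sd,
      n_replicates = cfg$synthetic$ic50_replicates,
      seed = derive_seed(cfg$seed, 300L + i),
      drug_id = "synthetic", target_id = kin[i])
    fit_ic50(series, flat_tol = cfg$ic50$flat_tol)
  })

  list(prediction = pred, kinome_table = ktab, filtered = filtered,
       records = records, partition = partition, screen = screen,
       accuracy = accuracy, ic50 = ic50_table(fits))
}
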