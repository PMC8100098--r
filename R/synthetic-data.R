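#' Specification for a planted-structure synthetic benchmark
#'
#' Describes an abstract-fingerprint world with planted chemotypes: each
#' target owns a disjoint "core" bit block shared by all of its ligands, and
#' each ligand adds private bits drawn from a common background region. Core
#' and background sizes are solved in closed form so that the expected
#' within-target and between-target Tanimoto similarities match
#' `chemotype_similarity` and `background_similarity`. Abstract bit sets are
#' the default so the ensemble statistics are testable without any chemistry
#' parsing.
#'
#' @param seed master seed; every generator output is a pure function of
#'   (spec, seed).
#' @param n_targets number of targets, default 20.
#' @param ligands_per_target ligands per target reference set, default 10.
#' @param chemotype_similarity expected within-target Tanimoto, default 0.7.
#' @param background_similarity expected between-target Tanimoto, default
#'   0.05 (must be below `chemotype_similarity`).
#' @param kind fingerprint kind label, default `"abstract"`.
#' @param fp_length fingerprint length, default 2048.
#' @param bits_per_ligand on-bits per ligand, default 64.
#' @param queries_per_target planted query compounds per target, default 3.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 7L, n_targets = 20L, ligands_per_target = 10L,
                           chemotype_similarity = 0.7,
                           background_similarity = 0.05,
                           kind = "abstract", fp_length = 2048L,
                           bits_per_ligand = 64L, queries_per_target = 3L) {
  if (chemotype_similarity <= background_similarity) {
    svt_config_error("chemotype_similarity must exceed background_similarity")
  }
  if (chemotype_similarity <= 0 || chemotype_similarity > 1) {
    svt_config_error("chemotype_similarity must be in (0, 1]")
  }
  if (background_similarity < 0 || background_similarity >= 1) {
    svt_config_error("background_similarity must be in [0, 1)")
  }
  structure(list(seed = as.integer(seed), n_targets = as.integer(n_targets),
                 ligands_per_target = as.integer(ligands_per_target),
                 chemotype_similarity = chemotype_similarity,
                 background_similarity = background_similarity,
                 kind = kind, fp_length = as.integer(fp_length),
                 bits_per_ligand = as.integer(bits_per_ligand),
                 queries_per_target = as.integer(queries_per_target)),
            class = "synthetic_spec")
}

# closed-form bit allocation: with m on-bits per ligand, expected pairwise
# intersection i maps to Tc = i / (2m - i), so i = Tc * 2m / (1 + Tc).
# Within-target pairs share the core (c bits) plus chance overlap of their
# k = m - c private bits in the shared background region of size B
# (expected k^2/B); between-target pairs share only the background overlap.
plan_bits <- function(spec) {
  m <- spec$bits_per_ligand
  i_of <- function(tc) tc * 2 * m / (1 + tc)
  i_within <- i_of(spec$chemotype_similarity)
  i_between <- i_of(spec$background_similarity)
  core <- round(i_within - i_between)
  if (core < 0) core <- 0L
  if (core > m) core <- m
  k <- m - core
  bg <- if (k > 0L && i_between > 0) round(k^2 / i_between) else 0L
  if (bg > 0L && bg < k) {
    svt_config_error("infeasible similarity targets: background region smaller than the private bit count")
  }
  # bg == 0 with k > 0 means background_similarity == 0: private bits must be
  # globally unique, allocated sequentially after the cores
  n_private <- if (bg == 0L) {
    spec$n_targets * (spec$ligands_per_target + spec$queries_per_target) * k
  } else 0L
  need <- spec$n_targets * core + bg + n_private
  if (need > spec$fp_length) {
    svt_config_error(sprintf(
      "infeasible similarity targets: need %d bits but fingerprint length is %d",
      need, spec$fp_length))
  }
  list(m = m, core = as.integer(core), k = as.integer(k), bg = as.integer(bg))
}

#' Generate a planted-chemotype SEA reference with known truth
#'
#' @param spec a [synthetic_spec()].
#' @return list: `reference` (a [sea_reference]), `queries` (named list of
#'   single-compound [fp_set]s), `truth` (data frame `compound_id`,
#'   `target_id` of the planted associations), `plan` (the bit allocation),
#'   `spec`.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  plan <- plan_bits(spec)
  target_ids <- sprintf("T%02d", seq_len(spec$n_targets))
  core_of <- function(t) {
    if (plan$core == 0L) integer(0)
    else (t - 1L) * plan$core + seq_len(plan$core) - 1L
  }
  bg_start <- spec$n_targets * plan$core
  private_counter <- new.env(parent = emptyenv())
  private_counter$next_bit <- bg_start + plan$bg
  draw_member <- function(t) {
    priv <- if (plan$k == 0L) {
      integer(0)
    } else if (plan$bg > 0L) {
      bg_start + sample.int(plan$bg, plan$k) - 1L
    } else {
      # zero background similarity: globally unique private bits
      b <- private_counter$next_bit + seq_len(plan$k) - 1L
      private_counter$next_bit <- private_counter$next_bit + plan$k
      b
    }
    fingerprint_new(c(core_of(t), priv), spec$kind, spec$fp_length)
  }
  with_seed(spec$seed, {
    sets <- lapply(seq_len(spec$n_targets), function(t) {
      fps <- lapply(seq_len(spec$ligands_per_target), function(l) draw_member(t))
      fp_set(fps, ids = sprintf("%s_L%02d", target_ids[t],
                                seq_len(spec$ligands_per_target)))
    })
    names(sets) <- target_ids
    queries <- list()
    truth <- NULL
    if (spec$queries_per_target > 0L) {
      truth <- do.call(rbind, lapply(seq_len(spec$n_targets), function(t) {
        data.frame(compound_id = sprintf("Q_%s_%02d", target_ids[t],
                                         seq_len(spec$queries_per_target)),
                   target_id = target_ids[t], stringsAsFactors = FALSE)
      }))
      queries <- lapply(seq_len(nrow(truth)), function(i) {
        t <- match(truth$target_id[i], target_ids)
        fp_set(list(draw_member(t)), ids = truth$compound_id[i])
      })
      names(queries) <- truth$compound_id
    }
    list(reference = sea_reference(sets), queries = queries, truth = truth,
         plan = plan, spec = spec)
  })
}

#' Generate a synthetic kinase-panel table
#'
#' Residual activities are drawn from Gaussians around `active_mean` for the
#' true actives and `inactive_mean` for the rest, truncated at 0 (blank =
#' 100). Reproducible from the seed.
#'
#' @param true_actives character vector of kinase ids that are genuinely
#'   inhibited (must be a subset of the generated vocabulary).
#' @param n_kinases total kinases in the panel.
#' @param active_mean,inactive_mean Gaussian means; the recommended design
#'   keeps `active_mean < screening threshold < inactive_mean`.
#' @param noise_sd Gaussian SD in percentage points, default 5.
#' @param seed integer seed.
#' @param concentration assay concentration echoed in the table, default 25.
#' @param kinases optional kinase id vector of length `n_kinases`; defaults
#'   to `KIN001..`.
#' @return Panel data frame in [read_panel()] layout, with attribute
#'   `truth` = `true_actives`.
#' @export
generate_panel <- function(true_actives, n_kinases, active_mean = 50,
                           inactive_mean = 95, noise_sd = 5, seed = 1L,
                           concentration = 25, kinases = NULL) {
  kinases <- kinases %||% sprintf("KIN%03d", seq_len(n_kinases))
  if (length(kinases) != n_kinases) svt_stop("kinases must have length n_kinases")
  if (length(setdiff(true_actives, kinases))) {
    svt_stop("true_actives must be a subset of the panel kinases")
  }
  is_active <- kinases %in% true_actives
  act <- with_seed(seed, {
    mu <- ifelse(is_active, active_mean, inactive_mean)
    pmax(0, mu + noise_sd * stats::rnorm(n_kinases))
  })
  out <- data.frame(kinase_name = paste0(kinases, "(h)"), gene_symbol = kinases,
                    entrez_id = seq_len(n_kinases),
                    concentration = concentration, activity_pct = act,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- true_actives
  out
}

#' Generate a noisy 4PL dose-response series
#'
#' `response(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)` plus
#' Gaussian noise; the generating parameters are recorded in attribute
#' `truth` for recovery tests.
#'
#' @param ic50,hill,top,bottom generating 4PL parameters (`ic50` should lie
#'   within the series range).
#' @param series concentration vector, e.g. [make_dilution_series()].
#' @param noise_sd Gaussian noise SD in percentage points.
#' @param n_replicates replicate curves.
#' @param seed integer seed.
#' @param drug_id,target_id identifiers for the series.
#' @return A [dose_response_series()] with attribute `truth`.
#' @export
generate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   series = make_dilution_series(100),
                                   noise_sd = 3, n_replicates = 3, seed = 23L,
                                   drug_id = "synthetic", target_id = "TGT") {
  truth <- list(ic50 = ic50, hill = hill, top = top, bottom = bottom)
  mu <- logistic4(series, bottom, top, ic50, hill)
  resp <- with_seed(seed, {
    t(vapply(seq_len(n_replicates),
             function(r) mu + noise_sd * stats::rnorm(length(series)),
             numeric(length(series))))
  })
  out <- dose_response_series(drug_id, target_id, series, resp)
  attr(out, "truth") <- truth
  out
}
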