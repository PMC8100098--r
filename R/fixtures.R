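#' Load the packaged worked-example tables
#'
#' The package ships, as plain CSV/TSV fixtures, the printed tables of the
#' worked example it was built around: the 40-component input set with
#' PubChem CIDs, the known/predicted/common target partition counts, the
#' 30-kinase panel screen at 25 µg/mL, the per-provenance validation
#' accuracies, the 14 kinases retested at 250 µg/mL with dose-dependence
#' flags, and the four reported IC50s. One high-dose activity (CLK1) is
#' typographically ambiguous in the source and is stored as missing with a
#' note rather than a guessed number.
#'
#' @return Named list: `components` (40 rows), `partition_counts`,
#'   `panel_25` (30 panel measurements, [read_panel()] layout), `accuracy`,
#'   `dose_pairs` (14 rows), `ic50` (4 rows), `kinase_vocabulary`.
#' @export
load_paper_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "seavote")
  list(
    components = utils::read.csv(ext("table1_components.csv"),
                                 stringsAsFactors = FALSE),
    partition_counts = utils::read.csv(ext("table2_partition_counts.csv"),
                                       stringsAsFactors = FALSE),
    panel_25 = read_panel(ext("table3_panel_25ug.csv")),
    accuracy = utils::read.csv(ext("table4_accuracy.csv"),
                               stringsAsFactors = FALSE),
    dose_pairs = utils::read.csv(ext("table5_dose_pairs.csv"),
                                 stringsAsFactors = FALSE),
    ic50 = utils::read.csv(ext("table6_ic50.csv"), stringsAsFactors = FALSE),
    kinase_vocabulary = read_kinase_vocabulary()
  )
}
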