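#' Reference panel and marker tables from a published plasma miRNA MCI study
#'
#' Two small plain-text tables shipped with the package, taken from the
#' printed results of a published two-class (cognitively normal vs mild
#' cognitive impairment) plasma miRNA qPCR study: the 85-assay panel that
#' survived quality filtering, and its 20 differential-correlation marker
#' pairs with the printed per-class Spearman correlations, score, log10
#' p-value and single-pair AUC. They serve as worked-example inputs: the
#' score column can be recomputed from the correlation columns with
#' [diff_score()], and the selection rule `|r1 - r2| > 0.8` can be replayed
#' on them.
#'
#' @return `reference_panel_assays()`: character vector of 85 assay IDs.
#'   `reference_marker_pairs()`: data.frame with columns `rank`,
#'   `molecule_a`, `molecule_b`, `score`, `log10_p`, `auc`, `r1`, `r2`.
#' @export
reference_marker_pairs <- function() {
  utils::read.delim(system.file("extdata", "mci_marker_pairs.tsv",
                                package = "dcmarker"),
                    stringsAsFactors = FALSE)
}

#' @rdname reference_marker_pairs
#' @export
reference_panel_assays <- function() {
  readLines(system.file("extdata", "panel_assays.txt", package = "dcmarker"))
}
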