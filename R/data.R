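#' Published annotation TP/FP counts of a dual-stain melanoma study
#'
#' True-positive and false-positive nucleus counts, printed precisions with
#' Wilson 95% intervals, and annotation rates for several annotation
#' applications (thresholding with brown or red chromogen, 3-band and
#' 6-band CNN annotators) evaluated in primary melanomas and in metastasis
#' subgroups. These printed counts are the reference inputs for validating
#' the statistics module: every precision and interval can be recomputed
#' from `fp`/`tp`.
#'
#' The aggregate metastasis normal-cell row is internally inconsistent in
#' its source: its printed TP (1113) differs from the sum of the printed
#' subgroup TPs (1148), and the printed interval derives from the subgroup
#' sum. The columns `ci_fp`/`ci_tp` therefore carry the counts that the
#' printed interval was computed from; they equal `fp`/`tp` for every other
#' row.
#'
#' @return Data frame with columns `cohort`, `label_type`, `app`, `site`,
#'   `fp`, `tp`, `precision_pct`, `ci_low_pct`, `ci_high_pct`,
#'   `rate_per_mm2`, `ci_fp`, `ci_tp`.
#' @export
#' @examples
#' head(example_annotation_counts())
example_annotation_counts <- function() {
  read.csv(system.file("extdata", "annotation_counts.csv",
                       package = "dualstain"),
           stringsAsFactors = FALSE)
}
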