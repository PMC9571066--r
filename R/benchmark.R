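#' Published benchmark: window-size sweep on a training set
#'
#' Event counts from a published evaluation of the dynamic-threshold
#' morphological spike filter on 136 candidate events (113 true ripples,
#' 2 sharp transients, 21 true spikes) detected by the RMS ripple detector
#' in clinical iEEG: for each opening-window size, the numbers of true
#' positives, false positives and false negatives, together with the
#' printed sensitivity and FDR percentages. Shipped as a plain-text
#' fixture so the package's SE/FDR/ROC arithmetic can be checked against
#' published numbers without access to patient data.
#'
#' Note the printed percentage columns are reproduced verbatim: a few rows
#' are internally inconsistent with SE = TP/(TP+FN) and FDR = FP/(FP+TP)
#' by 1-2 points (e.g. the 8 ms row prints 53% where the counts give 51%).
#' The package asserts the formulas, not those discrepant cells.
#'
#' @return a data.frame with columns `window_ms`, `TP`, `FP`, `detections`,
#'   `FN`, `sensitivity_pct_printed`, `fdr_pct_printed`.
#' @export
benchmark_sweep_table <- function() {
  utils::read.csv(system.file("extdata", "benchmark_sweep_training.csv",
                              package = "morphripple", mustWork = TRUE),
                  comment.char = "#")
}

#' Published benchmark: held-out test set at the 4 ms window
#'
#' Counts for one testing set of 4 candidate events (2 ripples, 2 spikes)
#' classified with the 4 ms opening window.
#'
#' @return a one-row data.frame with the same columns as
#'   [benchmark_sweep_table()].
#' @export
benchmark_test_table <- function() {
  utils::read.csv(system.file("extdata", "benchmark_test_4ms.csv",
                              package = "morphripple", mustWork = TRUE),
                  comment.char = "#")
}
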