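#' Prediction and evaluation parameters
#'
#' Bundles the tunable constants of the NoLS detection pipeline. The
#' defaults are the published operating point of NoD: 13-residue windows
#' over a 12-group alphabet, segments of 8 consecutive windows (hence a
#' minimum called length of 13 + 8 - 1 = 20 residues), a calling threshold
#' of 0.8 on the mean window score, a 60% minimum interval overlap for a
#' prediction to count as correct, and a 50-residue cap on experimental
#' NoLSs admitted to evaluation.
#'
#' @param window_length sliding-window size in residues.
#' @param alphabet_size number of reduced-alphabet groups.
#' @param consecutive_windows number of consecutive windows averaged into
#'   one candidate segment score.
#' @param score_threshold segment score at or above which a candidate
#'   segment is called (inclusive).
#' @param min_overlap_fraction minimum fraction of the shorter interval that
#'   the intersection must cover for a predicted/experimental pair to match.
#' @param max_test_nols_length longest experimental NoLS (inclusive length)
#'   admitted to evaluation.
#' @param strict_length_filter if `TRUE`, use strict `<` instead of `<=`
#'   against `max_test_nols_length`.
#'
#' @return A list of class `nols_params`. `segment_length` is derived:
#'   `window_length + consecutive_windows - 1`.
#' @export
#' @examples
#' nols_params()$segment_length  # 20
nols_params <- function(window_length = 13L,
                        alphabet_size = 12L,
                        consecutive_windows = 8L,
                        score_threshold = 0.8,
                        min_overlap_fraction = 0.6,
                        max_test_nols_length = 50L,
                        strict_length_filter = FALSE) {
  stopifnot(window_length >= 1L, consecutive_windows >= 1L,
            score_threshold > 0, score_threshold <= 1,
            min_overlap_fraction > 0, min_overlap_fraction <= 1,
            max_test_nols_length >= 1L)
  structure(list(
    window_length = as.integer(window_length),
    alphabet_size = as.integer(alphabet_size),
    consecutive_windows = as.integer(consecutive_windows),
    score_threshold = score_threshold,
    min_overlap_fraction = min_overlap_fraction,
    max_test_nols_length = as.integer(max_test_nols_length),
    strict_length_filter = isTRUE(strict_length_filter),
    segment_length = as.integer(window_length + consecutive_windows - 1L)
  ), class = "nols_params")
}
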