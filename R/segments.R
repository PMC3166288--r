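#' Candidate 20-residue segment scores
#'
#' NoLS calling operates on 20-residue candidate segments: the score of the
#' segment starting at residue `i` is the arithmetic mean of the 8
#' consecutive window scores `i..i+7` that it spans (13 + 8 - 1 = 20). A
#' segment score is defined only where all 8 windows exist, so a sequence
#' shorter than 20 residues has an empty candidate profile.
#'
#' @param profile a `nols_profile` from [score_windows()].
#' @param params a [nols_params()].
#' @return An object of class `nols_segment_profile`: list with `name`,
#'   `length` and `segment_scores` (named by segment start,
#'   `1..L - 19`).
#' @export
candidate_scores <- function(profile, params = nols_params()) {
  stopifnot(inherits(profile, "nols_profile"))
  k <- params$consecutive_windows
  n_win <- length(profile$scores)
  n_seg <- max(0L, n_win - k + 1L)
  if (n_seg == 0L) {
    seg <- numeric(0)
  } else {
    cs <- cumsum(c(0, profile$scores))
    seg <- (cs[(k + 1):(n_win + 1)] - cs[1:n_seg]) / k
    names(seg) <- seq_len(n_seg)
  }
  out <- list(name = profile$name, length = profile$length,
              segment_scores = seg)
  class(out) <- "nols_segment_profile"
  out
}

#' Call NoLS intervals from segment scores
#'
#' Every 20-residue candidate segment with score at or above the threshold
#' (default 0.8, inclusive) is positive; overlapping positive segments —
#' in particular maximal runs of consecutive positive starts `a..b`, which
#' merge into `[a, b + 19]` — coalesce into one called interval. This
#' merging is what produces called NoLSs longer than 20 residues. Positive
#' segments whose spans do not overlap stay separate intervals, even if
#' they touch. With no positive segment the result is an empty interval
#' set ("no NoLS predicted").
#'
#' @param segments a `nols_segment_profile` from [candidate_scores()].
#' @param record the [sequence_record()] the profile was computed from
#'   (used to attach the spanned residues); optional.
#' @param params a [nols_params()].
#' @return A data frame with columns `start`, `end` (1-based inclusive) and
#'   `sequence`; zero rows when nothing is called. Every called interval
#'   spans at least 20 residues; intervals are sorted and non-overlapping.
#' @export
call_nols <- function(segments, record = NULL, params = nols_params()) {
  stopifnot(inherits(segments, "nols_segment_profile"))
  seg_len <- params$segment_length
  pos <- segments$segment_scores >= params$score_threshold
  if (!length(pos) || !any(pos)) {
    return(data.frame(start = integer(), end = integer(),
                      sequence = character()))
  }
  starts_pos <- which(unname(pos))  # already sorted
  start <- integer(0); end <- integer(0)
  cur_start <- starts_pos[1]
  cur_end <- starts_pos[1] + seg_len - 1L
  for (s in starts_pos[-1]) {
    if (s <= cur_end) {             # segments overlap: extend
      cur_end <- s + seg_len - 1L
    } else {
      start <- c(start, cur_start); end <- c(end, cur_end)
      cur_start <- s; cur_end <- s + seg_len - 1L
    }
  }
  start <- c(start, cur_start); end <- c(end, cur_end)
  sequence <- if (!is.null(record)) {
    residues <- if (inherits(record, "nols_record")) record$residues else record
    substring(residues, start, end)
  } else {
    rep(NA_character_, length(start))
  }
  data.frame(start = start, end = end, sequence = sequence)
}

#' Per-residue score profile
#'
#' Expands segment scores to one value per residue for plotting and the
#' FULL/COMPLETE output formats: residue `i` (for `i <= L - 19`) carries the
#' score of the segment starting at `i`; the trailing residues
#' `L-18..L`, which start no complete segment, repeat the final segment
#' score so that every residue has a value. Sequences shorter than 20
#' residues get an all-zero profile (no segment is defined).
#'
#' @param segments a `nols_segment_profile`.
#' @param length sequence length; defaults to the profile's own.
#' @return Numeric vector of exactly `length` values.
#' @export
residue_profile <- function(segments, length = segments$length) {
  stopifnot(inherits(segments, "nols_segment_profile"))
  seg <- segments$segment_scores
  if (!base::length(seg)) return(rep(0, length))
  c(unname(seg), rep(unname(seg[base::length(seg)]), length - base::length(seg)))
}

#' End-to-end NoLS prediction for one sequence
#'
#' Convenience wrapper: score windows, average into candidate segments and
#' call intervals.
#'
#' @inheritParams score_windows
#' @param params a [nols_params()].
#' @return List with `profile` (window scores), `segments` (candidate
#'   segment scores), `intervals` (called NoLSs) and `residue_scores`.
#' @export
predict_nols <- function(model, record, structure = NULL,
                         params = nols_params()) {
  if (is.character(record)) record <- sequence_record("unnamed", record)
  profile <- score_windows(model, record, structure)
  segments <- candidate_scores(profile, params)
  intervals <- call_nols(segments, record, params)
  list(profile = profile, segments = segments, intervals = intervals,
       residue_scores = residue_profile(segments, nchar(record$residues)))
}

#' Plot the per-residue NoLS score profile
#'
#' Line chart of the 20-residue segment score at each residue, with the
#' calling band (threshold to 1) shaded as the NoLS candidate segment
#' region. Requires ggplot2.
#'
#' @param segments a `nols_segment_profile`.
#' @param params a [nols_params()] (provides the threshold).
#' @return A ggplot object.
#' @export
plot_nols_profile <- function(segments, params = nols_params()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_nols_profile() requires the ggplot2 package")
  }
  df <- data.frame(position = seq_len(segments$length),
                   score = residue_profile(segments))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = params$score_threshold, ymax = 1,
                      alpha = 0.2, fill = "pink") +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Residue position", y = "NoLS segment score",
                  title = segments$name) +
    ggplot2::theme_minimal()
}
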