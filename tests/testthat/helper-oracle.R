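# Independent brute-force reimplementations used as oracles; they must stay
# loop-based and naive, never sharing code with the package internals.

# mean of the k window scores covering each candidate segment, one at a time
brute_segment_scores <- function(window_scores, k = 8L) {
  n_seg <- length(window_scores) - k + 1L
  if (n_seg < 1L) return(numeric(0))
  out <- numeric(n_seg)
  for (i in seq_len(n_seg)) out[i] <- mean(window_scores[i:(i + k - 1L)])
  out
}

# test every 20-mer independently, then union overlapping positive segments
# by repeated pairwise merging until a fixed point
brute_call <- function(window_scores, threshold = 0.8, seg_len = 20L, k = 8L) {
  seg <- brute_segment_scores(window_scores, k)
  pos <- which(seg >= threshold)
  if (!length(pos)) return(data.frame(start = integer(), end = integer()))
  iv <- data.frame(start = pos, end = pos + seg_len - 1L)
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(iv))) {
      for (j in seq_len(nrow(iv))) {
        if (i >= j || i > nrow(iv) || j > nrow(iv)) next
        if (iv$start[j] <= iv$end[i] && iv$start[i] <= iv$end[j]) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# wrap raw window scores as the profile object the caller consumes
fake_profile <- function(scores, length = base::length(scores) + 12L,
                         name = "test") {
  out <- list(name = name, length = length, scores = scores,
              too_short = FALSE)
  class(out) <- "nols_profile"
  out
}

random_window <- function(n = 13L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
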