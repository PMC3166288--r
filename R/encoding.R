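#' Enumerate sliding windows over a sequence
#'
#' Step-1 sliding windows of `window_length` residues. A sequence shorter
#' than the window length cannot be scored: a condition of class
#' `nols_too_short` is signalled so that batch callers can report "no
#' prediction" instead of aborting.
#'
#' @param record a [sequence_record()] (or plain residue string).
#' @param window_length window size in residues.
#' @return A data frame with columns `start` (1-based first residue,
#'   `1..L - window_length + 1`) and `window` (the residue substring).
#' @export
#' @examples
#' nrow(sequence_windows("MGRNKKKKRDGDDRRPRLVL"))  # 8 windows for L = 20
sequence_windows <- function(record, window_length = 13L) {
  residues <- if (inherits(record, "nols_record")) record$residues else record
  L <- nchar(residues)
  if (L < window_length) {
    stop(structure(class = c("nols_too_short", "error", "condition"),
                   list(message = paste0("sequence of length ", L,
                                         " is shorter than the window length ",
                                         window_length),
                        call = sys.call(-1))))
  }
  starts <- seq_len(L - window_length + 1L)
  data.frame(start = starts,
             window = substring(residues, starts, starts + window_length - 1L))
}

#' One-hot encode a single window
#'
#' Sparse binary encoding of a 13-residue window: position `p` (0-based)
#' holding a residue of reduced-alphabet group `g` (1-based) sets bit
#' `p * 12 + g`. Exactly 13 bits are set in the amino-acid block. When a
#' 3-state secondary-structure string (over `H`/`E`/`C`) is supplied, a
#' trailing block of 13 x 3 one-hot structure bits is appended, giving
#' feature length 195 instead of 156.
#'
#' @param window residue string of length `window_length`.
#' @param alphabet a [reduced_alphabet()].
#' @param structure optional structure string of the same length over
#'   `H` (helix), `E` (strand), `C` (coil).
#' @param window_length expected window size.
#' @return Integer 0/1 vector of length `window_length * 12` (plus
#'   `window_length * 3` with the structure channel).
#' @export
encode_window <- function(window, alphabet = default_alphabet(),
                          structure = NULL, window_length = 13L) {
  if (nchar(window) != window_length) {
    stop("window must have exactly ", window_length, " residues, got ",
         nchar(window))
  }
  chars <- strsplit(toupper(window), "")[[1]]
  g <- unname(alphabet$index[chars])
  if (anyNA(g)) {
    bad <- which(is.na(g))[1]
    stop("non-standard residue '", chars[bad], "' at window position ", bad)
  }
  n_groups <- length(alphabet$groups)
  bits <- integer(window_length * n_groups)
  bits[(seq_len(window_length) - 1L) * n_groups + g] <- 1L
  if (!is.null(structure)) {
    bits <- c(bits, encode_structure_block(structure, window_length))
  }
  bits
}

encode_structure_block <- function(structure, window_length) {
  if (nchar(structure) != window_length) {
    stop("structure string must have ", window_length, " states, got ",
         nchar(structure))
  }
  states <- match(strsplit(toupper(structure), "")[[1]], c("H", "E", "C"))
  if (anyNA(states)) {
    stop("structure states must be one of H/E/C")
  }
  block <- integer(window_length * 3L)
  block[(seq_len(window_length) - 1L) * 3L + states] <- 1L
  block
}

#' Encode every window of a sequence as a feature matrix
#'
#' Vectorised equivalent of applying [encode_window()] to each window of
#' [sequence_windows()]. Row `i` is the window starting at residue `i`.
#'
#' @inheritParams encode_window
#' @param record a [sequence_record()] or residue string.
#' @param structure optional per-residue structure string for the whole
#'   sequence (same length as the sequence); window slices are taken
#'   internally.
#' @return Integer matrix, one row per window, with `rownames` the window
#'   start positions.
#' @export
encode_windows <- function(record, alphabet = default_alphabet(),
                           structure = NULL, window_length = 13L) {
  residues <- if (inherits(record, "nols_record")) record$residues else record
  wins <- sequence_windows(residues, window_length)
  chars <- strsplit(toupper(residues), "")[[1]]
  g <- unname(alphabet$index[chars])
  if (anyNA(g)) {
    bad <- which(is.na(g))[1]
    stop("non-standard residue '", chars[bad], "' at position ", bad,
         "; run clean_sequence() first")
  }
  n_groups <- length(alphabet$groups)
  n_win <- nrow(wins)
  feat_len <- window_length * n_groups
  X <- matrix(0L, nrow = n_win, ncol = feat_len)
  pos_offsets <- (seq_len(window_length) - 1L) * n_groups
  for (p in seq_len(window_length)) {
    cols <- pos_offsets[p] + g[wins$start + p - 1L]
    X[cbind(seq_len(n_win), cols)] <- 1L
  }
  if (!is.null(structure)) {
    if (nchar(structure) != nchar(residues)) {
      stop("structure string length (", nchar(structure),
           ") must equal sequence length (", nchar(residues), ")")
    }
    states <- match(strsplit(toupper(structure), "")[[1]], c("H", "E", "C"))
    if (anyNA(states)) stop("structure states must be one of H/E/C")
    S <- matrix(0L, nrow = n_win, ncol = window_length * 3L)
    s_offsets <- (seq_len(window_length) - 1L) * 3L
    for (p in seq_len(window_length)) {
      S[cbind(seq_len(n_win), s_offsets[p] + states[wins$start + p - 1L])] <- 1L
    }
    X <- cbind(X, S)
  }
  rownames(X) <- wins$start
  X
}

#' Feature-vector length for a configuration
#'
#' @param alphabet a [reduced_alphabet()].
#' @param use_structure whether the 3-state structure channel is enabled.
#' @param window_length window size in residues.
#' @return Integer: `13 * 12 = 156` by default, `195` with structure.
#' @export
feature_length <- function(alphabet = default_alphabet(),
                           use_structure = FALSE, window_length = 13L) {
  as.integer(window_length * (length(alphabet$groups) + if (use_structure) 3L else 0L))
}
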