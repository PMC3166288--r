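#' Model of a planted NoLS-like motif
#'
#' Synthetic proteins are background residues drawn i.i.d. from a
#' background composition, with planted motifs whose residues are drawn
#' from a lysine/arginine-enriched composition — the defining feature of
#' nucleolar localization sequences. Defaults: motif length uniform on
#' 15–40 residues; motif composition K = 0.30, R = 0.25 (K+R = 0.55) with
#' the remaining mass uniform over the other 18 residues; uniform
#' background.
#'
#' @param length_range integer two-vector, inclusive bounds of the uniform
#'   motif-length distribution (minimum 13, one full window).
#' @param motif_probs named numeric vector of residue probabilities inside
#'   motifs (summing to 1, names in the 20 standard residues).
#' @param background_probs residue probabilities outside motifs.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(length_range = c(15L, 40L),
                        motif_probs = default_motif_probs(),
                        background_probs = stats::setNames(
                          rep(1 / 20, 20), AA_STANDARD)) {
  stopifnot(length(length_range) == 2L, length_range[1] >= 13L,
            length_range[2] >= length_range[1])
  check_probs <- function(p, what) {
    if (is.null(names(p)) || !setequal(names(p), AA_STANDARD)) {
      stop(what, " must be named by the 20 standard residues")
    }
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop(what, " must be non-negative and sum to 1")
    }
    p[AA_STANDARD]
  }
  structure(list(length_range = as.integer(length_range),
                 motif_probs = check_probs(motif_probs, "motif_probs"),
                 background_probs = check_probs(background_probs,
                                                "background_probs")),
            class = "motif_model")
}

#' @rdname motif_model
#' @export
default_motif_probs <- function() {
  p <- stats::setNames(rep(0.45 / 18, 20), AA_STANDARD)
  p["K"] <- 0.30
  p["R"] <- 0.25
  p
}

draw_residues <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate one synthetic protein with planted motifs
#'
#' Background residues are i.i.d. from the background composition; each of
#' `n_motifs` motifs (length drawn from the model's range) is planted at a
#' uniformly chosen position such that motifs do not overlap. Deterministic
#' given `seed`.
#'
#' @param length protein length in residues (>= 20).
#' @param model a [motif_model()].
#' @param n_motifs number of motifs to plant (0 for a pure-background
#'   protein).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param name record name.
#' @return List with `record` (a [sequence_record()]) and `truth` (data
#'   frame of planted `start`/`end` intervals, zero rows if `n_motifs` is
#'   0).
#' @export
generate_protein <- function(length, model = motif_model(), n_motifs = 1L,
                             seed = NULL, name = "synthetic") {
  stopifnot(length >= 20L, n_motifs >= 0L)
  gen <- function() {
    chars <- strsplit(draw_residues(length, model$background_probs), "")[[1]]
    truth <- data.frame(start = integer(), end = integer())
    if (n_motifs > 0L) {
      lens <- sample(seq(model$length_range[1], model$length_range[2]),
                     n_motifs, replace = TRUE)
      if (sum(lens) > length) {
        stop(n_motifs, " motifs of total length ", sum(lens),
             " cannot be placed in a protein of length ", length)
      }
      # place motifs left to right in the slack left by earlier ones
      starts <- integer(n_motifs)
      cursor <- 1L
      remaining <- sum(lens)
      for (i in seq_len(n_motifs)) {
        slack <- length - remaining - cursor + 1L
        if (slack < 0L) {
          stop("motifs cannot be placed without overlap in a protein of length ",
               length)
        }
        starts[i] <- cursor + sample.int(slack + 1L, 1L) - 1L
        cursor <- starts[i] + lens[i]
        remaining <- remaining - lens[i]
      }
      for (i in seq_len(n_motifs)) {
        motif <- strsplit(draw_residues(lens[i], model$motif_probs), "")[[1]]
        chars[starts[i]:(starts[i] + lens[i] - 1L)] <- motif
      }
      truth <- data.frame(start = starts, end = starts + lens - 1L)
    }
    list(record = sequence_record(name, paste(chars, collapse = "")),
         truth = truth)
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Generate a labeled window corpus for training
#'
#' Positive 13-mers are sampled from within planted motifs (one window per
#' motif, at a uniform offset); negatives are windows of pure-background
#' proteins. A per-class holdout split is flagged for early-stopping or
#' held-out evaluation. Deterministic given `seed`.
#'
#' @param n_pos,n_neg number of positive / negative windows.
#' @param model a [motif_model()].
#' @param seed RNG seed.
#' @param holdout_fraction fraction of each class flagged `holdout`.
#' @param window_length window size in residues.
#' @return Data frame with columns `window` (13-mer string), `label`
#'   (1 positive / 0 negative) and `split` (`"train"` or `"holdout"`).
#' @export
generate_training_set <- function(n_pos, n_neg, model = motif_model(),
                                  seed = 1L, holdout_fraction = 0.2,
                                  window_length = 13L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            holdout_fraction >= 0, holdout_fraction < 1)
  with_local_seed(seed, {
    pos <- vapply(seq_len(n_pos), function(i) {
      len <- sample(seq(model$length_range[1], model$length_range[2]), 1L)
      motif <- draw_residues(len, model$motif_probs)
      off <- sample.int(len - window_length + 1L, 1L)
      substr(motif, off, off + window_length - 1L)
    }, character(1))
    neg <- vapply(seq_len(n_neg), function(i) {
      draw_residues(window_length, model$background_probs)
    }, character(1))
    split_flags <- function(n) {
      k <- floor(holdout_fraction * n)
      flags <- rep("train", n)
      if (k > 0) flags[sample.int(n, k)] <- "holdout"
      flags
    }
    data.frame(window = c(pos, neg),
               label = c(rep(1L, n_pos), rep(0L, n_neg)),
               split = c(split_flags(n_pos), split_flags(n_neg)),
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic corpus as FASTA plus a truth TSV
#'
#' Generates `n_proteins` synthetic proteins (each with `n_motifs` planted
#' motifs), writes them as FASTA and the planted intervals as a
#' tab-separated truth table with columns `name`, `start`, `end` — the
#' ground-truth companion used by end-to-end tests.
#'
#' @param n_proteins number of proteins.
#' @param length protein length in residues.
#' @param model a [motif_model()].
#' @param n_motifs motifs per protein.
#' @param seed RNG seed.
#' @param fasta,truth output paths.
#' @return Invisibly, a list with the `records` and the `truth` data frame.
#' @export
write_synthetic_corpus <- function(n_proteins, length = 300L,
                                   model = motif_model(), n_motifs = 1L,
                                   seed = 1L, fasta, truth) {
  sims <- with_local_seed(seed, {
    lapply(seq_len(n_proteins), function(i) {
      generate_protein(length, model, n_motifs,
                       name = sprintf("synthetic_%04d", i))
    })
  })
  records <- lapply(sims, `[[`, "record")
  truth_df <- do.call(rbind, lapply(sims, function(s) {
    if (!nrow(s$truth)) return(NULL)
    cbind(name = s$record$name, s$truth)
  }))
  if (is.null(truth_df)) truth_df <- data.frame(name = character(),
                                                start = integer(),
                                                end = integer())
  if (!missing(fasta)) write_fasta(records, fasta)
  if (!missing(truth)) {
    utils::write.table(truth_df, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(records = records, truth = truth_df))
}
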