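sigmoid <- function(x) 1 / (1 + exp(-x))

# run code with a fixed RNG state, restoring the caller's state afterwards
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Initialise a window-scoring neural network
#'
#' A single-hidden-layer feed-forward network with logistic activations
#' throughout, mapping one encoded window (156 bits, or 195 with the
#' structure channel) to a score in the closed interval `[0, 1]`. Weights
#' are initialised uniformly in `[-r, r]` from the given seed.
#'
#' @param alphabet a [reduced_alphabet()]; serialized with the model so that
#'   predictions are reproducible.
#' @param hidden_size number of hidden units.
#' @param use_structure whether the input includes the 13 x 3 structure block.
#' @param window_length window size in residues.
#' @param seed RNG seed for weight initialisation.
#' @param init_range half-width of the uniform initialisation interval.
#' @return An object of class `nols_model` with weight matrices `W1`
#'   (input x hidden), `b1`, `w2` (hidden), `b2`, and `training` metadata.
#' @export
nols_model <- function(alphabet = default_alphabet(), hidden_size = 10L,
                       use_structure = FALSE, window_length = 13L,
                       seed = 1L, init_range = 0.5) {
  d <- feature_length(alphabet, use_structure, window_length)
  with_local_seed(seed, {
    W1 <- matrix(runif(d * hidden_size, -init_range, init_range), d, hidden_size)
    b1 <- runif(hidden_size, -init_range, init_range)
    w2 <- runif(hidden_size, -init_range, init_range)
    b2 <- runif(1, -init_range, init_range)
  })
  structure(list(alphabet = alphabet,
                 window_length = as.integer(window_length),
                 use_structure = isTRUE(use_structure),
                 input_size = d,
                 hidden_size = as.integer(hidden_size),
                 activation = "logistic",
                 W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 training = list(trained = FALSE, seed = seed)),
            class = "nols_model")
}

#' @export
print.nols_model <- function(x, ...) {
  cat("NoLS window scorer: ", x$input_size, " inputs -> ", x$hidden_size,
      " logistic hidden units -> 1 logistic output\n", sep = "")
  cat("  alphabet: ", x$alphabet$name,
      if (x$use_structure) "  (+ 3-state structure channel)", "\n", sep = "")
  if (isTRUE(x$training$trained)) {
    cat("  trained: ", x$training$epochs_run, " epochs on ",
        x$training$n_pos, " positive / ", x$training$n_neg,
        " negative windows (seed ", x$training$seed, ")\n", sep = "")
  } else {
    cat("  untrained (random initialisation, seed ", x$training$seed, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Score encoded windows with the network
#'
#' Deterministic forward pass. Accepts a single feature vector or a matrix
#' with one window per row.
#'
#' @param model a [nols_model()].
#' @param features 0/1 feature vector of length `model$input_size`, or a
#'   matrix with that many columns.
#' @return Numeric score(s) in `[0, 1]`.
#' @export
forward <- function(model, features) {
  stopifnot(inherits(model, "nols_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$input_size) {
    stop("feature length mismatch: model expects ", model$input_size,
         " inputs but got ", ncol(features))
  }
  H <- sigmoid(sweep(features %*% model$W1, 2, model$b1, `+`))
  p <- sigmoid(drop(H %*% model$w2) + model$b2)
  unname(p)
}

#' Per-window score profile of a sequence
#'
#' Encodes every 13-residue window of the (cleaned) sequence and scores it,
#' producing one score per window start `1..L-12`. A sequence shorter than
#' the window length yields an empty profile flagged `too_short` (with a
#' warning) rather than an error, so batch runs never abort.
#'
#' @param model a [nols_model()].
#' @param record a [sequence_record()] or residue string.
#' @param structure optional per-residue 3-state structure string (required
#'   iff the model was built with `use_structure = TRUE`).
#' @return An object of class `nols_profile`: list with `name`, `length`,
#'   `scores` (named by window start) and `too_short`.
#' @export
score_windows <- function(model, record, structure = NULL) {
  stopifnot(inherits(model, "nols_model"))
  if (is.character(record)) record <- sequence_record("unnamed", record)
  if (model$use_structure && is.null(structure)) {
    stop("model expects a secondary-structure string but none was supplied")
  }
  if (!model$use_structure && !is.null(structure)) {
    stop("model was built without the structure channel")
  }
  L <- nchar(record$residues)
  if (L < model$window_length) {
    warning("sequence '", record$name, "' (", L,
            " residues) is shorter than the window length ",
            model$window_length, "; no windows scored")
    return(new_nols_profile(record$name, L, numeric(0), too_short = TRUE))
  }
  X <- encode_windows(record, model$alphabet, structure, model$window_length)
  scores <- forward(model, X)
  names(scores) <- rownames(X)
  new_nols_profile(record$name, L, scores, too_short = FALSE)
}

new_nols_profile <- function(name, length, scores, too_short = FALSE) {
  out <- list(name = name, length = length, scores = scores,
              too_short = too_short)
  class(out) <- "nols_profile"
  out
}

#' Train the window scorer
#'
#' Full-batch gradient descent with momentum on weighted binary
#' cross-entropy. Classes receive equal effective weight by default so that
#' a large negative set (background windows) does not swamp the positives.
#' Training stops early when the monitored loss has not improved by
#' `tol` for `patience` consecutive epochs. Fully deterministic given
#' `seed`, which drives weight initialisation and data shuffling.
#'
#' @param positives,negatives character vectors of window strings (length
#'   `window_length`), or pre-encoded feature matrices.
#' @param alphabet a [reduced_alphabet()].
#' @param hidden_size hidden-layer width.
#' @param epochs maximum number of epochs.
#' @param learning_rate gradient-descent step size.
#' @param momentum momentum coefficient.
#' @param class_weights length-2 vector of relative effective weights for
#'   (positive, negative); each class's window weights are scaled so the
#'   class totals are in this ratio.
#' @param validation_fraction fraction of windows held out (per class) to
#'   monitor early stopping; 0 monitors the training loss instead.
#' @param patience epochs without improvement before stopping.
#' @param tol minimum loss decrease counted as an improvement.
#' @param seed RNG seed; all randomness flows from it.
#' @param use_structure build the model with the structure input block
#'   (training windows must then be pre-encoded matrices).
#' @param window_length window size in residues.
#' @return A trained [nols_model()]; `model$training` records the seed,
#'   epochs run, loss history and data summary.
#' @export
train_model <- function(positives, negatives,
                        alphabet = default_alphabet(),
                        hidden_size = 10L, epochs = 300L,
                        learning_rate = 2, momentum = 0.9,
                        class_weights = c(1, 1),
                        validation_fraction = 0.1,
                        patience = 25L, tol = 1e-5,
                        seed = 1L, use_structure = FALSE,
                        window_length = 13L) {
  if (length(positives) == 0L || NROW(positives) == 0L) stop("positive class is empty")
  if (length(negatives) == 0L || NROW(negatives) == 0L) stop("negative class is empty")
  enc <- function(x) {
    if (is.matrix(x)) return(x)
    t(vapply(x, encode_window, integer(feature_length(alphabet, use_structure,
                                                      window_length)),
             alphabet = alphabet, window_length = window_length,
             USE.NAMES = FALSE))
  }
  Xp <- enc(positives)
  Xn <- enc(negatives)
  X <- rbind(Xp, Xn)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xn)))
  # per-window weights: class totals proportional to class_weights
  w <- c(rep(class_weights[1] / nrow(Xp), nrow(Xp)),
         rep(class_weights[2] / nrow(Xn), nrow(Xn)))

  model <- nols_model(alphabet, hidden_size, use_structure, window_length,
                      seed = seed)
  n <- nrow(X)
  with_local_seed(seed + 1L, {
    ord <- sample.int(n)
  })
  X <- X[ord, , drop = FALSE]; y <- y[ord]; w <- w[ord]
  if (validation_fraction > 0 && n >= 10L) {
    n_val <- max(2L, floor(validation_fraction * n))
    val <- seq_len(n_val)
    Xv <- X[val, , drop = FALSE]; yv <- y[val]; wv <- w[val]
    X <- X[-val, , drop = FALSE]; y <- y[-val]; w <- w[-val]
  } else {
    Xv <- NULL
  }
  w <- w / sum(w)
  if (!is.null(Xv)) wv <- wv / sum(wv)

  eps <- 1e-12
  wce <- function(p, yy, ww) -sum(ww * (yy * log(p + eps) + (1 - yy) * log(1 - p + eps)))

  W1 <- model$W1; b1 <- model$b1; w2 <- model$w2; b2 <- model$b2
  vW1 <- W1 * 0; vb1 <- b1 * 0; vw2 <- w2 * 0; vb2 <- 0
  best <- Inf; best_state <- NULL; stall <- 0L
  loss_history <- numeric(0)

  for (epoch in seq_len(epochs)) {
    Z1 <- sweep(X %*% W1, 2, b1, `+`)
    H <- sigmoid(Z1)
    p <- sigmoid(drop(H %*% w2) + b2)
    loss <- wce(p, y, w)
    if (!is.finite(loss)) {
      stop("non-finite training loss at epoch ", epoch,
           " (learning rate ", learning_rate, "); reduce the step size")
    }
    loss_history <- c(loss_history, loss)

    d2 <- w * (p - y)                      # dL/dz2, n-vector
    gw2 <- drop(crossprod(H, d2))
    gb2 <- sum(d2)
    dH <- outer(d2, w2) * H * (1 - H)      # n x h
    gW1 <- crossprod(X, dH)
    gb1 <- colSums(dH)

    vW1 <- momentum * vW1 - learning_rate * gW1
    vb1 <- momentum * vb1 - learning_rate * gb1
    vw2 <- momentum * vw2 - learning_rate * gw2
    vb2 <- momentum * vb2 - learning_rate * gb2
    W1 <- W1 + vW1; b1 <- b1 + vb1; w2 <- w2 + vw2; b2 <- b2 + vb2

    monitored <- if (is.null(Xv)) loss else {
      Hv <- sigmoid(sweep(Xv %*% W1, 2, b1, `+`))
      wce(sigmoid(drop(Hv %*% w2) + b2), yv, wv)
    }
    if (monitored < best - tol) {
      best <- monitored; stall <- 0L
      best_state <- list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  if (!is.null(best_state)) {
    W1 <- best_state$W1; b1 <- best_state$b1
    w2 <- best_state$w2; b2 <- best_state$b2
  }
  model$W1 <- W1; model$b1 <- b1; model$w2 <- w2; model$b2 <- b2
  model$training <- list(trained = TRUE, seed = seed,
                         epochs_run = length(loss_history),
                         n_pos = nrow(Xp), n_neg = nrow(Xn),
                         class_weights = class_weights,
                         learning_rate = learning_rate, momentum = momentum,
                         validation_fraction = validation_fraction,
                         loss_history = loss_history,
                         best_monitored_loss = best)
  model
}

MODEL_FORMAT_VERSION <- "1.0"

# column-major %.17g representation; 17 significant digits round-trip any
# IEEE double exactly through as.numeric()
num_to_chr <- function(x) sprintf("%.17g", as.vector(x))
chr_to_num <- function(x) as.numeric(unlist(x))

#' Save / load a model as versioned plain text
#'
#' JSON with full-precision weights; the file is self-describing (embeds the
#' alphabet, feature configuration and a fingerprint) so that a loaded model
#' reproduces forward outputs bit-identically and refuses to load against a
#' corrupted or mismatching alphabet.
#'
#' @param model a [nols_model()].
#' @param path file path.
#' @return `load_model()` returns the restored `nols_model`; `save_model()`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nols_model"))
  payload <- list(
    format = "nolscan-model",
    version = MODEL_FORMAT_VERSION,
    alphabet = list(name = model$alphabet$name,
                    groups = lapply(model$alphabet$groups, paste, collapse = ""),
                    fingerprint = alphabet_fingerprint(model$alphabet)),
    window_length = model$window_length,
    use_structure = model$use_structure,
    input_size = model$input_size,
    hidden_size = model$hidden_size,
    activation = model$activation,
    # weights as %.17g strings: exact decimal round-trip for every double
    weights = list(W1 = num_to_chr(model$W1), b1 = num_to_chr(model$b1),
                   w2 = num_to_chr(model$w2), b2 = num_to_chr(model$b2)),
    training = model$training[setdiff(names(model$training), "loss_history")]
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("cannot parse model file '",
                                               path, "': ", conditionMessage(e)))
  if (!identical(payload$format, "nolscan-model")) {
    stop("'", path, "' is not a nolscan model file")
  }
  if (!identical(payload$version, MODEL_FORMAT_VERSION)) {
    stop("model file version ", payload$version,
         " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  }
  groups <- unlist(payload$alphabet$groups)
  alphabet <- reduced_alphabet(groups, name = payload$alphabet$name)
  if (!identical(alphabet_fingerprint(alphabet), payload$alphabet$fingerprint)) {
    stop("alphabet fingerprint mismatch in '", path,
         "': file is corrupted or the embedded alphabet was altered")
  }
  W1 <- matrix(chr_to_num(payload$weights$W1), nrow = payload$input_size,
               ncol = payload$hidden_size)
  model <- structure(list(alphabet = alphabet,
                          window_length = as.integer(payload$window_length),
                          use_structure = isTRUE(payload$use_structure),
                          input_size = as.integer(payload$input_size),
                          hidden_size = as.integer(payload$hidden_size),
                          activation = payload$activation,
                          W1 = W1,
                          b1 = chr_to_num(payload$weights$b1),
                          w2 = chr_to_num(payload$weights$w2),
                          b2 = chr_to_num(payload$weights$b2),
                          training = payload$training),
                     class = "nols_model")
  expected <- feature_length(alphabet, model$use_structure, model$window_length)
  if (model$input_size != expected) {
    stop("model input size ", model$input_size,
         " inconsistent with its feature configuration (expected ", expected, ")")
  }
  model
}
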