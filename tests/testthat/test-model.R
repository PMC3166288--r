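test_that("forward pass is a bounded logistic composition", {
  m <- nols_model(hidden_size = 4, seed = 1)
  m$W1[] <- 0; m$b1[] <- 0; m$w2[] <- 0; m$b2 <- 0
  expect_equal(forward(m, encode_window(random_window())), 0.5)

  # hand-set tiny network: z1 = 13*0.01 + 0.1, p = sigmoid(2*sigmoid(z1) - 1)
  m <- nols_model(hidden_size = 1, seed = 1)
  m$W1[] <- 0.01; m$b1[] <- 0.1; m$w2[] <- 2; m$b2 <- -1
  expect_equal(forward(m, encode_window("MKRDESTNQILVF")),
               0.52859269834436884, tolerance = 1e-15)

  # bounded in [0,1] for arbitrary finite weights
  set.seed(2)
  for (i in 1:20) {
    m$W1[] <- rnorm(length(m$W1), sd = 50)
    m$b1[] <- rnorm(1, sd = 50); m$w2[] <- rnorm(1, sd = 50)
    m$b2 <- rnorm(1, sd = 50)
    p <- forward(m, encode_window(random_window()))
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("dimension mismatches are reported with expected/actual sizes", {
  m <- nols_model(seed = 1)
  expect_error(forward(m, rep(1, 100)), "156.*100")
})

test_that("score_windows aligns one score per window start", {
  m <- cached_model()
  seq20 <- paste0(strrep("K", 10), strrep("A", 10))
  prof <- score_windows(m, seq20)
  expect_length(prof$scores, 8)
  expect_equal(names(prof$scores), as.character(1:8))
  expect_false(prof$too_short)

  # equals mapping forward over windows one at a time
  wins <- sequence_windows(seq20)
  loop <- vapply(wins$window, function(w) forward(m, encode_window(w)),
                 numeric(1), USE.NAMES = FALSE)
  expect_equal(unname(prof$scores), loop)

  expect_warning(prof <- score_windows(m, strrep("K", 12)), "shorter")
  expect_true(prof$too_short)
  expect_length(prof$scores, 0)
})

test_that("training separates a separable toy problem and is deterministic", {
  pos <- replicate(30, paste(sample(c("K", "R"), 13, TRUE), collapse = ""))
  neg <- replicate(30, paste(sample(c("D", "E"), 13, TRUE), collapse = ""))
  m1 <- train_model(pos, neg, hidden_size = 3, seed = 5,
                    validation_fraction = 0)
  enc <- function(w) encode_window(w)
  acc <- mean(c(vapply(pos, function(w) forward(m1, enc(w)), 1) > 0.5,
                vapply(neg, function(w) forward(m1, enc(w)), 1) < 0.5))
  expect_equal(acc, 1.0)
  expect_lt(tail(m1$training$loss_history, 1),
            m1$training$loss_history[1])

  m2 <- train_model(pos, neg, hidden_size = 3, seed = 5,
                    validation_fraction = 0)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$b1, m2$b1)
  expect_identical(m1$w2, m2$w2)
  expect_identical(m1$b2, m2$b2)
  expect_true(m1$training$trained)

  expect_error(train_model(character(0), neg), "positive class is empty")
  expect_error(train_model(pos, character(0)), "negative class is empty")
})

test_that("training on the synthetic corpus scores held-out windows well", {
  corpus <- generate_training_set(400, 400, seed = 42)
  m <- cached_model()  # trained on the train split of this corpus
  ho <- corpus[corpus$split == "holdout", ]
  X <- t(vapply(ho$window, encode_window, integer(156), USE.NAMES = FALSE))
  p <- forward(m, X)
  y <- ho$label
  r <- rank(p)
  auroc <- (sum(r[y == 1]) - sum(y == 1) * (sum(y == 1) + 1) / 2) /
    (sum(y == 1) * sum(y == 0))
  expect_gt(auroc, 0.9)
})

test_that("label-flipped training anti-correlates with the original", {
  corpus <- generate_training_set(200, 200, seed = 13)
  tr <- corpus[corpus$split == "train", ]
  ho <- corpus[corpus$split == "holdout", ]
  m_fwd <- train_model(tr$window[tr$label == 1], tr$window[tr$label == 0],
                       seed = 13)
  m_rev <- train_model(tr$window[tr$label == 0], tr$window[tr$label == 1],
                       seed = 13)
  X <- t(vapply(ho$window, encode_window, integer(156), USE.NAMES = FALSE))
  expect_lt(cor(forward(m_fwd, X), forward(m_rev, X)), 0)
})

test_that("model files round-trip bit-identically", {
  m <- cached_model()
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_identical(m2$W1, m$W1)
  expect_identical(m2$b1, m$b1)
  expect_identical(m2$w2, m$w2)
  expect_identical(m2$b2, m$b2)

  set.seed(77)
  wins <- replicate(100, random_window())
  X <- t(vapply(wins, encode_window, integer(156), USE.NAMES = FALSE))
  expect_identical(forward(m, X), forward(m2, X))
})

test_that("corrupted or foreign model files are rejected", {
  m <- cached_model()
  tf <- withr::local_tempfile(fileext = ".json")
  save_model(m, tf)

  txt <- readLines(tf)
  tampered <- sub('"basic": "KR"', '"basic": "KRH"', txt, fixed = TRUE)
  tampered <- sub('"bulky": "HW"', '"bulky": "W"', tampered, fixed = TRUE)
  tf2 <- withr::local_tempfile(fileext = ".json")
  writeLines(tampered, tf2)
  expect_error(load_model(tf2), "fingerprint")

  tf3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', tf3)
  expect_error(load_model(tf3), "not a nolscan model")

  writeLines(sub('"version": "1.0"', '"version": "9.9"', txt, fixed = TRUE), tf3)
  expect_error(load_model(tf3), "version")
})
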