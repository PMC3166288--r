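test_that("candidate segment scores are 8-window means", {
  prof <- fake_profile(rep(1, 20), length = 32)
  seg <- candidate_scores(prof)
  expect_length(seg$segment_scores, 13)
  expect_true(all(seg$segment_scores == 1))

  prof <- fake_profile(c(rep(1, 8), rep(0, 5)))
  seg <- candidate_scores(prof)
  expect_equal(unname(seg$segment_scores[1]), 1.0)
  expect_equal(unname(seg$segment_scores[2]), 7 / 8)

  # shorter than one segment: empty profile
  expect_length(candidate_scores(fake_profile(runif(7), length = 19))$segment_scores, 0)

  set.seed(31)
  for (i in 1:20) {
    scores <- runif(sample(8:60, 1))
    seg <- candidate_scores(fake_profile(scores))
    expect_equal(unname(seg$segment_scores), brute_segment_scores(scores))
  }
})

test_that("call_nols merges positive segments into the published interval shapes", {
  params <- nols_params()
  # exactly one positive segment at start 1 -> minimum-length interval 1-20
  seq32 <- strrep("A", 32)
  seg <- candidate_scores(fake_profile(c(rep(0.8, 8), rep(0, 12)), length = 32))
  iv <- call_nols(seg, seq32, params)
  expect_equal(iv$start, 1)
  expect_equal(iv$end, 20)
  expect_equal(iv$sequence, strrep("A", 20))

  # all segments positive -> one full-length interval
  seg <- candidate_scores(fake_profile(rep(1, 20), length = 32))
  iv <- call_nols(seg, seq32, params)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(1, 32))

  # positive starts {5..11, 40} -> 5-30 and 40-59
  seg_scores <- rep(0, 45)
  seg_scores[c(5:11, 40)] <- 0.95
  seg <- list(name = "x", length = 64, segment_scores = seg_scores)
  class(seg) <- "nols_segment_profile"
  iv <- call_nols(seg, strrep("A", 64), params)
  expect_equal(iv$start, c(5, 40))
  expect_equal(iv$end, c(30, 59))

  # nothing positive -> empty call
  seg <- candidate_scores(fake_profile(rep(0.5, 20), length = 32))
  expect_equal(nrow(call_nols(seg, seq32, params)), 0)
})

test_that("threshold comparison is inclusive at 0.8", {
  seg <- candidate_scores(fake_profile(rep(0.8, 8), length = 20))
  expect_equal(nrow(call_nols(seg, strrep("A", 20))), 1)
  seg <- candidate_scores(fake_profile(rep(0.8 - 1e-9, 8), length = 20))
  expect_equal(nrow(call_nols(seg, strrep("A", 20))), 0)
})

test_that("caller equals the brute-force 20-mer oracle on random profiles", {
  set.seed(99)
  params <- nols_params()
  for (i in 1:200) {
    L <- sample(13:200, 1)
    # mix smooth and spiky profiles so positive runs of many shapes occur
    scores <- if (i %% 2) runif(L - 12, 0.5, 1) else runif(L - 12)
    prof <- fake_profile(scores, length = L)
    got <- call_nols(candidate_scores(prof, params), strrep("A", L), params)
    want <- brute_call(scores)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    if (nrow(got)) {
      expect_true(all(got$end - got$start + 1 >= 20))
      expect_true(all(got$end <= L))
      if (nrow(got) > 1) expect_true(all(diff(got$start) > 0))
    }
    # determinism
    again <- call_nols(candidate_scores(prof, params), strrep("A", L), params)
    expect_identical(got, again)
  }
})

test_that("raising the threshold never increases called coverage", {
  set.seed(41)
  for (i in 1:20) {
    L <- sample(40:150, 1)
    prof <- fake_profile(runif(L - 12, 0.4, 1), length = L)
    covered <- function(thr) {
      iv <- call_nols(candidate_scores(prof),
                      params = nols_params(score_threshold = thr))
      sum(iv$end - iv$start + 1)
    }
    cov <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99), covered, numeric(1))
    expect_true(all(diff(cov) <= 0))
  }
})

test_that("residue profiles pad the trailing residues with the last segment score", {
  seg <- candidate_scores(fake_profile(rep(0.3, 20), length = 32))
  expect_equal(residue_profile(seg), rep(0.3, 32))

  seg <- list(name = "x", length = 21, segment_scores = c(a = 0.1, b = 0.9))
  class(seg) <- "nols_segment_profile"
  expect_equal(residue_profile(seg), c(0.1, rep(0.9, 20)))

  set.seed(6)
  for (i in 1:10) {
    L <- sample(13:100, 1)
    seg <- candidate_scores(fake_profile(runif(max(0, L - 12)), length = L))
    expect_length(residue_profile(seg), L)
  }

  # undefined below one segment: all zero
  seg <- candidate_scores(fake_profile(runif(5), length = 17))
  expect_equal(residue_profile(seg), rep(0, 17))
})
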