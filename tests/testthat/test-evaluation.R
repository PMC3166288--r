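test_that("overlap_fraction reproduces the worked benchmark pairs", {
  expect_equal(overlap_fraction(c(129, 143), c(120, 143)), 1.0)
  expect_equal(overlap_fraction(c(31, 64), c(27, 49)), 19 / 23)
  expect_equal(overlap_fraction(c(1, 47), c(22, 60)), 26 / 39)
  expect_equal(overlap_fraction(c(1, 10), c(20, 30)), 0)
})

test_that("overlap_fraction is symmetric and 1 under containment", {
  set.seed(17)
  for (i in 1:50) {
    a <- sort(sample(1:300, 2)); b <- sort(sample(1:300, 2))
    expect_equal(overlap_fraction(a, b), overlap_fraction(b, a))
    f <- overlap_fraction(a, b)
    expect_gte(f, 0); expect_lte(f, 1)
    inner <- c(a[1] + 1, a[2]) # contained in a (when valid)
    if (inner[1] <= inner[2]) {
      expect_equal(overlap_fraction(a, inner), 1)
    }
  }
  expect_error(overlap_fraction(c(10, 5), c(1, 3)), "invalid interval")
})

test_that("the length filter keeps NoLSs up to 50 residues inclusive", {
  expect_true(length_filter(c(129, 143)))
  expect_true(length_filter(c(51, 100)))   # inclusive length exactly 50
  expect_false(length_filter(c(1, 60)))
  strict <- nols_params(strict_length_filter = TRUE)
  expect_false(length_filter(c(51, 100), strict))
  expect_true(length_filter(c(52, 100), strict))
})

test_that("classification is many-to-many at the 60% criterion", {
  nsa2 <- evaluation_record("NP_055701",
                            data.frame(start = c(10, 131), end = c(41, 154)),
                            data.frame(start = 133, end = 155))
  cls <- classify_record(nsa2)
  expect_equal(cls$detected, c(FALSE, TRUE))
  expect_equal(cls$tp, TRUE)
  expect_false(cls$has_false_positive)

  nobp <- evaluation_record("NP_081208",
                            data.frame(start = 220, end = 262),
                            data.frame(start = c(230, 276), end = c(255, 306)))
  cls <- classify_record(nobp)
  expect_equal(cls$detected, TRUE)
  expect_equal(cls$tp, c(TRUE, FALSE))
  expect_true(cls$has_false_positive)

  none <- evaluation_record("x",
                            data.frame(start = c(1, 50), end = c(20, 90)),
                            data.frame(start = integer(), end = integer()))
  cls <- classify_record(none)
  expect_equal(cls$detected, c(FALSE, FALSE))
  expect_length(cls$tp, 0)
  expect_false(cls$has_false_positive)
})

test_that("detected + missed and tp + fp partition each record", {
  for (rec in nod_benchmark()) {
    cls <- classify_record(rec)
    expect_length(cls$detected, nrow(rec$experimental))
    expect_length(cls$tp, nrow(rec$predicted))
    expect_equal(sum(cls$detected) + sum(!cls$detected),
                 nrow(rec$experimental))
    expect_equal(sum(cls$tp) + sum(!cls$tp), nrow(rec$predicted))
  }
})

test_that("the packaged benchmark has the published composition", {
  recs <- nod_benchmark()
  expect_length(recs, 27)
  expect_equal(sum(vapply(recs, function(r) nrow(r$experimental), 1L)), 31)
  expect_equal(sum(vapply(recs, function(r) nrow(r$predicted), 1L)), 28)
  esag8 <- Filter(function(r) r$accession == "CAD21884", recs)[[1]]
  expect_equal(nrow(esag8$predicted), 0)
  expect_equal(esag8$group, "Trypanosomes")
})

test_that("metrics aggregate correctly and ignore record order", {
  perfect <- evaluation_record("p", data.frame(start = 10, end = 40),
                               data.frame(start = 12, end = 38),
                               group = "G")
  m <- compute_metrics(list(perfect))
  row <- m[m$level == "overall", ]
  expect_equal(c(row$sensitivity, row$ppv, row$specificity), c(1, 1, 1))

  recs <- nod_benchmark()
  m1 <- compute_metrics(recs)
  set.seed(4)
  m2 <- compute_metrics(sample(recs))
  ov1 <- m1[m1$level == "overall", -(1:2)]
  ov2 <- m2[m2$level == "overall", -(1:2)]
  expect_equal(ov1, ov2, ignore_attr = TRUE)
  for (g in m1$label[m1$level == "group"]) {
    expect_equal(m1[m1$label == g, -(1:2)], m2[m2$label == g, -(1:2)],
                 ignore_attr = TRUE)
  }
})

test_that("experimental NoLSs over the length cap are excluded before matching", {
  rec <- evaluation_record("p",
                           data.frame(start = c(1, 100), end = c(80, 120)),
                           data.frame(start = 5, end = 60),
                           group = "G")
  # the 80-residue NoLS is dropped; its matching prediction becomes an FP
  m <- compute_metrics(list(rec))
  ov <- m[m$level == "overall", ]
  expect_equal(ov$nols, 1)
  expect_equal(ov$tp, 0)
  expect_equal(ov$fp, 1)
})

test_that("ppv is undefined (NA) when nothing is predicted", {
  rec <- evaluation_record("p", data.frame(start = 1, end = 30),
                           data.frame(start = integer(), end = integer()),
                           group = "G")
  m <- compute_metrics(list(rec))
  ov <- m[m$level == "overall", ]
  expect_true(is.na(ov$ppv))
  expect_equal(ov$sensitivity, 0)
  expect_equal(ov$specificity, 1)
})

test_that("metrics tables export as TSV", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(compute_metrics(nod_benchmark()), tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), 18)  # 9 groups + 8 species + overall
  expect_equal(back$tp[back$level == "overall"], 22)
})
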