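test_that("exact agreement gives TP = TB with no errors", {
  m <- match_beats(c(100, 300, 500), c(100, 300, 500), fs = 200)
  expect_equal(m$tp, 3)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
  expect_equal(m$tb, 3)
  expect_equal(m$tp + m$fn, m$tb)
})

test_that("a detection just outside the window is both FP and FN", {
  fs <- 360
  m <- match_beats(1000 + 0.15 * fs + 1, 1000, fs = fs)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))
  # just inside matches
  m2 <- match_beats(1000 + 0.15 * fs, 1000, fs = fs)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1, 0, 0))
})

test_that("matching is one-to-one: one detection cannot clear two annotations", {
  # brute force over matchings: with a single detection the maximum
  # cardinality is 1, so TP = 1, FN = 1, FP = 0
  m <- match_beats(1030, c(1000, 1060), fs = 360)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 1))
  # nearest wins, ties to the earlier detection
  m2 <- match_beats(c(995, 1005), 1000, fs = 360)
  expect_equal(m2$tp, 1)
  expect_equal(tidy(m2)$detection, 995)
})

test_that("unsorted inputs are rejected", {
  expect_error(match_beats(c(10, 5), c(1, 2), fs = 200), "increasing")
  expect_error(match_beats(c(1, 2), c(10, 5), fs = 200), "increasing")
})

test_that("swapping detected and annotated swaps FP and FN", {
  set.seed(55)
  for (i in 1:10) {
    a <- sort(sample(1:5000, 20))
    b <- sort(sample(1:5000, 25))
    a <- a[c(TRUE, diff(a) > 0)]
    b <- b[c(TRUE, diff(b) > 0)]
    m1 <- match_beats(a, b, fs = 200)
    m2 <- match_beats(b, a, fs = 200)
    expect_equal(m1$tp, m2$tp)
    expect_equal(m1$fp, m2$fn)
    expect_equal(m1$fn, m2$fp)
  }
})

test_that("small uniform shifts of well-separated beats keep TP intact", {
  fs <- 200
  ann <- seq(500, 10000, by = 2 * 0.15 * fs * 2 + 40) # gaps > 2x tolerance
  for (shift in c(-25, -10, 10, 25)) { # |shift| < 30-sample tolerance
    m <- match_beats(ann + shift, ann, fs = fs)
    expect_equal(m$tp, length(ann))
  }
})

test_that("metric formulas reproduce direct arithmetic", {
  m <- beat_counts(tp = 90, fp = 10, fn = 10)
  expect_equal(sensitivity(m), 90)
  expect_equal(ppv(m), 90)
  expect_equal(accuracy(m), 100 * 90 / 110)
  expect_equal(f1_score(m), 90)
  expect_equal(total_error_rate(m), 20)
  expect_equal(failed_detection(m), 20)

  perfect <- beat_counts(tp = 50, fp = 0, fn = 0)
  expect_equal(sensitivity(perfect), 100)
  expect_equal(ppv(perfect), 100)
  expect_equal(accuracy(perfect), 100)
  expect_equal(f1_score(perfect), 100)
  expect_equal(total_error_rate(perfect), 0)

  hopeless <- beat_counts(tp = 0, fp = 5, fn = 7)
  expect_equal(sensitivity(hopeless), 0)
  expect_equal(ppv(hopeless), 0)
  expect_equal(accuracy(hopeless), 0)
  expect_equal(f1_score(hopeless), 0)

  expect_warning(res <- total_error_rate(beat_counts(0, 0, 0, tb = 0)), "undefined")
  expect_true(is.na(res))
})

test_that("F1 is the harmonic mean of sensitivity and PPV; accuracy is the weakest metric", {
  set.seed(77)
  for (i in 1:50) {
    m <- beat_counts(tp = sample(1:500, 1), fp = sample(0:100, 1), fn = sample(0:100, 1))
    se <- sensitivity(m) / 100
    pp <- ppv(m) / 100
    expect_equal(f1_score(m) / 100, 2 * se * pp / (se + pp), tolerance = 1e-12)
    expect_lte(accuracy(m), min(sensitivity(m), ppv(m)) + 1e-12)
  }
})

test_that("aggregation bases agree on homogeneous input and expose imbalance", {
  one <- beat_counts(90, 10, 10, record_id = "r1")
  agg1 <- aggregate_metrics(one)
  expect_equal(agg1$sensitivity[1], agg1$sensitivity[2])
  expect_equal(agg1$sensitivity[1], 90)

  twin <- aggregate_metrics(list(one, beat_counts(90, 10, 10, record_id = "r2")))
  expect_equal(twin$ppv, c(90, 90))

  mixed <- aggregate_metrics(list(
    beat_counts(90, 10, 10, record_id = "a"),
    beat_counts(10, 0, 90, record_id = "b")
  ))
  pooled <- mixed[mixed$basis == "pooled", ]
  per <- mixed[mixed$basis == "per_record_mean", ]
  expect_equal(pooled$sensitivity, 50)
  expect_equal(per$sensitivity, 50)
  expect_equal(pooled$ppv, 100 * 100 / 110)
  expect_equal(per$ppv, 95)
})

test_that("the published benchmark counts load and obey the failed-detection identity", {
  counts <- reference_counts()
  expect_equal(nrow(counts), 12)
  expect_equal(counts$fp + counts$fn, counts$failed_detection)
  # the flagged-consistent rows really are; the flagged-inconsistent are not
  computed <- 100 * (counts$fp + counts$fn) / counts$tb
  ok <- counts$error_rate_consistent
  expect_equal(round(computed[ok], 2), counts$error_rate_pct[ok])
  expect_false(any(round(computed[!ok], 2) == counts$error_rate_pct[!ok]))
})
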