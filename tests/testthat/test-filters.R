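test_that("each filter stage matches its difference-equation transcription", {
  set.seed(101)
  for (rep in 1:3) {
    x <- rnorm(1000)
    expect_lt(max(abs(lowpass_filter(x) - oracle_lowpass(x))), 1e-9)
    expect_lt(max(abs(highpass_filter(x) - oracle_highpass(x))), 1e-9)
    expect_lt(max(abs(derivative_filter(x) - oracle_derivative(x))), 1e-9)
    expect_lt(max(abs(integrate_window(x^2, 30) - oracle_integrate(x^2, 30))), 1e-9)
  }
})

test_that("low-pass has DC gain 36 and impulse response summing to 36", {
  expect_equal(lowpass_filter(numeric(50)), numeric(50))
  y <- lowpass_filter(rep(1, 200))
  expect_equal(tail(y, 1), 36)
  expect_equal(max(abs(diff(tail(y, 50)))), 0) # steady state reached
  imp <- lowpass_filter(c(1, numeric(99)))
  expect_equal(sum(imp), 36)
})

test_that("high-pass rejects DC and passes zero through", {
  expect_equal(highpass_filter(numeric(64)), numeric(64))
  y <- highpass_filter(rep(1, 400))
  expect_lt(max(abs(tail(y, 100))), 1e-9)
})

test_that("derivative is zero on constants and constant on ramps", {
  y <- derivative_filter(rep(3.5, 50))
  expect_equal(y[5:50], numeric(46))
  r <- derivative_filter(as.numeric(0:99))
  # (2n + (n-1) - (n-3) - 2(n-4)) / 8 = 10/8 after the 4-sample transient
  expect_equal(unique(round(r[6:100], 12)), 1.25)
  expect_equal(derivative_filter(numeric(20)), numeric(20))
})

test_that("squaring is pointwise, non-negative and sign-blind", {
  expect_equal(square_signal(c(-2, 0, 3)), c(4, 0, 9))
  set.seed(7)
  x <- rnorm(100)
  expect_equal(square_signal(-x), square_signal(x))
  expect_true(all(square_signal(x) >= 0))
})

test_that("moving-window integration: plateau, warm-up, guards", {
  # impulse of height h -> plateau h/N for N samples
  h <- 12
  N <- 10
  x <- c(numeric(20), h, numeric(40))
  y <- integrate_window(x, N)
  expect_equal(y[21:30], rep(h / N, 10))
  expect_equal(y[31:61], numeric(31))
  # warm-up divides by samples actually present
  z <- integrate_window(rep(2, 45), 30)
  expect_equal(z, rep(2, 45))
  expect_error(integrate_window(rep(1, 5), 6), "exceeds")
  expect_error(integrate_window(rep(1, 5), 0), ">= 1")
})

test_that("linear stages are linear on random inputs", {
  set.seed(42)
  x <- rnorm(500)
  y <- rnorm(500)
  a <- 2.5
  b <- -1.25
  for (f in list(lowpass_filter, highpass_filter, derivative_filter)) {
    expect_lt(max(abs(f(a * x + b * y) - (a * f(x) + b * f(y)))), 1e-9)
  }
})

test_that("non-finite signals are rejected with a diagnostic", {
  expect_error(lowpass_filter(c(1, NA, 3)), "non-finite")
  expect_error(preprocess_ecg(c(1, Inf), fs = 200), "non-finite")
})

test_that("preprocess chains the stages and keeps the delay bookkeeping", {
  rec <- clean_record(fs = 200, duration_s = 30, hr_bpm = 60, seed = 5)
  proc <- preprocess_ecg(rec)
  expect_s3_class(proc, "ecg_processed")
  expect_equal(nrow(proc), nrow(rec))
  expect_true(all(proc$integrated >= 0))
  expect_equal(attr(proc, "window_samples"), 30)
  d <- attr(proc, "stage_delays")
  expect_equal(sum(d), 6 + 16 + 2 + d[["integration"]])
  # zero record -> zero everywhere
  zero <- preprocess_ecg(ecg_record(numeric(1000), fs = 200))
  expect_equal(zero$integrated, numeric(1000))
  expect_equal(zero$bandpassed, numeric(1000))
})

test_that("integrated track has one dominant hump per simulated beat", {
  rec <- clean_record(fs = 200, duration_s = 30, hr_bpm = 72, seed = 9)
  proc <- preprocess_ecg(rec)
  z <- proc$integrated
  thr <- max(z) / 2
  crossings <- sum(diff(z > thr) == 1)
  expect_equal(crossings, nrow(ecg_annotations(rec)))
})

test_that("resampling to 200 Hz preserves identity, annotations and frequency", {
  rec200 <- clean_record(fs = 200, duration_s = 10, seed = 2)
  expect_identical(resample_ecg_200hz(rec200), rec200)

  x <- sin(2 * pi * 3 * (0:4000) / 400)
  rec400 <- ecg_record(x, fs = 400, annotations = 800)
  out <- resample_ecg_200hz(rec400)
  expect_equal(ecg_fs(out), 200)
  expect_equal(ecg_annotations(out)$sample, 400L)

  x360 <- sin(2 * pi * 10 * (0:3599) / 360)
  out360 <- resample_ecg_200hz(ecg_record(x360, fs = 360))
  mods <- abs(fft(out360$amplitude))
  n <- nrow(out360)
  peak_hz <- (which.max(mods[1:(n / 2)]) - 1) / n * 200
  expect_equal(peak_hz, 10, tolerance = 0.05)
})

test_that("detection after resampling lands on the rescaled truth", {
  rec <- clean_record(fs = 360, duration_s = 40, hr_bpm = 75, seed = 13)
  res <- resample_ecg_200hz(rec)
  m <- detect_and_match(res)
  expect_equal(m$fn + m$fp, 0)
  # annotation-relative beat times within 1 output sample of native truth
  native <- detect_and_match(rec)
  expect_equal(m$tp, native$tp)
  expect_lte(max(abs(tidy(m)$delta_samples)), 1)
})
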