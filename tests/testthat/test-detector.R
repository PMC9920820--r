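test_that("peak-estimate updates follow the 0.125/0.875 rule", {
  expect_equal(update_signal_peak(5, 5), 5) # fixed point
  expect_equal(update_signal_peak(0, 8), 1)
  expect_equal(update_noise_peak(4, 0), 3.5)
  expect_equal(update_noise_peak(3, 3), 3)
  # identical formula for both estimates
  expect_equal(update_signal_peak(2.5, 7.5), update_noise_peak(2.5, 7.5))
  # geometric convergence to a constant peak height
  s <- 0
  for (i in 1:100) s <- update_signal_peak(s, 10)
  expect_lt(abs(s - 10), 1e-5 * 10)
  expect_error(update_signal_peak(-1, 2), "non-negative")
  expect_error(update_noise_peak(1, -2), "non-negative")
})

test_that("thresholds are the quarter-split of the peak estimates", {
  t0 <- compute_thresholds(8, 0)
  expect_equal(t0$threshold_f1, 2)
  expect_equal(t0$threshold_f2, 0.5)
  t1 <- compute_thresholds(10, 2)
  expect_equal(t1$threshold_f1, 4)
  expect_equal(t1$threshold_f2, 1)
  tc <- compute_thresholds(3, 3)
  expect_equal(tc$threshold_f1, 3)
  expect_equal(tc$threshold_f2, 0.75)
})

test_that("threshold sandwich holds for random non-degenerate states", {
  set.seed(31)
  for (i in 1:200) {
    npk <- runif(1, 0, 5)
    spk <- npk + runif(1, 0, 10)
    th <- compute_thresholds(spk, npk)
    expect_identical(th$threshold_f2, 0.25 * th$threshold_f1)
    expect_gte(th$threshold_f1, npk)
    expect_lte(th$threshold_f1, spk)
  }
})

test_that("RR statistics use the mean of up to eight intervals and the 1.66 limit", {
  s <- rr_stats(rep(160, 8))
  expect_equal(s$rr_average1, 160)
  expect_equal(s$rr_missed_limit, 265.6)
  expect_equal(rr_stats(c(100, 120, 140, 160, 180, 200, 220, 240))$rr_average1, 170)
  expect_equal(rr_stats(200)$rr_average1, 200)
  # only the most recent eight count
  expect_equal(rr_stats(c(1000, rep(100, 8)))$rr_average1, 100)
  expect_error(rr_stats(numeric()), "empty RR buffer")
})

test_that("a clean 60 bpm minute yields one detection per beat within 150 ms", {
  rec <- clean_record(fs = 200, duration_s = 60, hr_bpm = 60, seed = 1)
  det <- detect_qrs(preprocess_ecg(rec))
  truth <- ecg_annotations(rec)$sample
  expect_true(abs(nrow(det) - 60) <= 1)
  m <- match_beats(det, rec, fs = 200)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
  expect_lte(max(abs(tidy(m)$delta_samples)), 0.150 * 200)
})

test_that("zero signal produces zero detections", {
  det <- detect_qrs(preprocess_ecg(ecg_record(numeric(4000), fs = 200)))
  expect_equal(nrow(det), 0)
})

test_that("records shorter than the learning phase warn and return empty", {
  expect_warning(
    det <- detect_qrs(preprocess_ecg(ecg_record(rnorm(100), fs = 200))),
    "learning"
  )
  expect_equal(nrow(det), 0)
})

test_that("search-back recovers attenuated beats", {
  rec <- simulate_ecg(
    fs = 200, duration_s = 120, hr_bpm = 75, seed = 11,
    attenuate_every = 10, attenuate_factor = 0.3
  )
  proc <- preprocess_ecg(rec)
  on <- match_beats(detect_qrs(proc, search_back = TRUE), rec, fs = 200)
  off <- match_beats(detect_qrs(proc, search_back = FALSE), rec, fs = 200)
  expect_gte(sensitivity(on), 98)
  expect_gte(sensitivity(on) - sensitivity(off), 5)
})

test_that("detections are scale invariant", {
  rec <- clean_record(fs = 200, duration_s = 40, hr_bpm = 80, seed = 21, white_sd = 0.02)
  base <- detect_qrs(preprocess_ecg(rec))
  for (g in c(1000, 1e-3)) {
    scaled <- ecg_record(rec$amplitude * g, fs = 200,
                         annotations = ecg_annotations(rec))
    det <- detect_qrs(preprocess_ecg(scaled))
    expect_identical(det$sample, base$sample)
  }
})

test_that("detection is deterministic", {
  rec <- clean_record(fs = 360, duration_s = 30, hr_bpm = 70, seed = 8, white_sd = 0.05)
  proc <- preprocess_ecg(rec)
  expect_identical(
    detect_qrs(proc, detector = "ampt")$sample,
    detect_qrs(proc, detector = "ampt")$sample
  )
  expect_identical(
    detect_qrs(proc, detector = "pt")$sample,
    detect_qrs(proc, detector = "pt")$sample
  )
})

test_that("no two detections fall within the 200 ms refractory period", {
  for (seed in 1:3) {
    rec <- simulate_ecg(
      fs = 200, duration_s = 90, hr_bpm = 90, rhythm = "irregular",
      premature_prob = 0.15, white_sd = 0.05, seed = seed
    )
    det <- detect_qrs(preprocess_ecg(rec))
    expect_true(all(diff(det$sample) >= 0.2 * 200))
  }
})

test_that("truncation does not disturb detections before the causality horizon", {
  rec <- clean_record(fs = 200, duration_s = 60, hr_bpm = 75, seed = 17, white_sd = 0.03)
  full <- detect_qrs(preprocess_ecg(rec))
  horizon <- (0.200 + 0.075) * 200 # candidate suppression radius + slope window
  for (k in c(4000, 7000, 10000)) {
    part <- ecg_record(rec$amplitude[1:k], fs = 200)
    det_k <- detect_qrs(preprocess_ecg(part))
    cutoff <- k - 1 - horizon
    expect_identical(det_k$sample[det_k$sample < cutoff],
                     full$sample[full$sample < cutoff])
  }
})

test_that("raw-coordinate mapping lands on the simulated apex and stays in bounds", {
  rec <- clean_record(fs = 250, duration_s = 30, hr_bpm = 65, seed = 3)
  det <- detect_qrs(preprocess_ecg(rec))
  truth <- ecg_annotations(rec)$sample
  matched <- match_beats(det, rec, fs = 250)
  expect_lte(max(abs(tidy(matched)$delta_samples)), 1)

  proc <- preprocess_ecg(rec)
  delays <- attr(proc, "stage_delays")
  # indices near the record start are clipped, not out of bounds
  mapped <- map_peak_to_raw(c(0L, 5L), delays, proc$bandpassed, 250)
  expect_true(all(mapped >= 0 & mapped < nrow(rec)))
  # delay-only vs refined mapping never differ by more than the 75 ms window
  ints <- attr(det, "peaks_integrated")
  refined <- map_peak_to_raw(ints, delays, proc$bandpassed, 250)
  delay_only <- ints - sum(delays)
  expect_true(all(abs(refined - delay_only) <= 0.075 * 250 + 0.025 * 250 + 1))
})

test_that("tall peaked T waves are rejected by the slope rule, not detected", {
  rec <- simulate_ecg(fs = 200, duration_s = 120, hr_bpm = 100,
                      morphology = "tall_t", seed = 12)
  proc <- preprocess_ecg(rec)
  with_rule <- match_beats(detect_qrs(proc, twave_rule = TRUE), rec, fs = 200)
  without <- match_beats(detect_qrs(proc, twave_rule = FALSE), rec, fs = 200)
  expect_gte(without$fp, 10 * max(with_rule$fp, 1))
  expect_gte(sensitivity(with_rule), 99)
})
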