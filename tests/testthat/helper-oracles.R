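# Naive sample-by-sample transcriptions of the filter difference equations,
# written independently of the implementation (scalar loops, explicit
# zero history). These are the oracles the vectorised filters are checked
# against.

oracle_lowpass <- function(x) {
  y <- numeric(length(x))
  xx <- function(i) if (i >= 1 && i <= length(x)) x[i] else 0
  yy <- function(i) if (i >= 1) y[i] else 0
  for (n in seq_along(x)) {
    y[n] <- 2 * yy(n - 1) - yy(n - 2) + xx(n) - 2 * xx(n - 6) + xx(n - 12)
  }
  y
}

oracle_highpass <- function(x) {
  y <- numeric(length(x))
  xx <- function(i) if (i >= 1 && i <= length(x)) x[i] else 0
  yy <- function(i) if (i >= 1) y[i] else 0
  for (n in seq_along(x)) {
    y[n] <- yy(n - 1) + 32 * xx(n - 16) - 32 * xx(n - 17) - xx(n) + xx(n - 32)
  }
  y
}

oracle_derivative <- function(x) {
  y <- numeric(length(x))
  xx <- function(i) if (i >= 1 && i <= length(x)) x[i] else 0
  for (n in seq_along(x)) {
    y[n] <- (2 * xx(n) + xx(n - 1) - xx(n - 3) - 2 * xx(n - 4)) / 8
  }
  y
}

oracle_integrate <- function(x, N) {
  y <- numeric(length(x))
  for (n in seq_along(x)) {
    lo <- max(1, n - N + 1)
    y[n] <- mean(x[lo:n])
  }
  y
}

# Convenience: a short clean sinus record plus its conditioning output.
clean_record <- function(fs = 200, duration_s = 60, hr_bpm = 60, seed = 1, ...) {
  simulate_ecg(fs = fs, duration_s = duration_s, hr_bpm = hr_bpm, seed = seed, ...)
}

detect_and_match <- function(rec, ...) {
  det <- detect_qrs(preprocess_ecg(rec), ...)
  match_beats(det, rec, fs = ecg_fs(rec))
}
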