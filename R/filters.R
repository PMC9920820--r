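#' Pan-Tompkins signal-conditioning filters
#'
#' The four stages of the classical QRS conditioning chain, designed for a
#' 200 Hz sampling rate and applied causally with zero initial state:
#'
#' * `lowpass_filter()`: `y(n) = 2y(n-1) - y(n-2) + x(n) - 2x(n-6) + x(n-12)`,
#'   DC gain 36, nominal delay 6 samples.
#' * `highpass_filter()`: the all-pass-minus-low-pass section
#'   `y(n) = y(n-1) + 32x(n-16) - 32x(n-17) - x(n) + x(n-32)`, DC gain 0,
#'   delay 16 samples. Together the two give the ~5-15 Hz band-pass where QRS
#'   energy concentrates.
#' * `derivative_filter()`: the five-point derivative
#'   `y(n) = (2x(n) + x(n-1) - x(n-3) - 2x(n-4)) / 8`, delay 2 samples.
#' * `square_signal()`: pointwise squaring.
#' * `integrate_window()`: trailing moving-window mean over `window_samples`
#'   points (~150 ms); during warm-up the mean is taken over the samples
#'   actually available, so a startup spike is avoided.
#'
#' @param x Numeric vector of samples (finite).
#' @param window_samples Trailing window length in samples (>= 1, <= length(x)).
#' @return Numeric vector of the same length as `x`.
#' @seealso [preprocess_ecg()] which chains all stages.
#' @export
lowpass_filter <- function(x) {
  check_signal(x)
  b <- c(1, 0, 0, 0, 0, 0, -2, 0, 0, 0, 0, 0, 1)
  u <- causal_fir(x, b)
  as.numeric(stats::filter(u, c(2, -1), method = "recursive"))
}

#' @rdname lowpass_filter
#' @export
highpass_filter <- function(x) {
  check_signal(x)
  b <- numeric(33)
  b[1] <- -1    # x(n)
  b[17] <- 32   # x(n-16)
  b[18] <- -32  # x(n-17)
  b[33] <- 1    # x(n-32)
  u <- causal_fir(x, b)
  as.numeric(stats::filter(u, 1, method = "recursive"))
}

#' @rdname lowpass_filter
#' @export
derivative_filter <- function(x) {
  check_signal(x)
  causal_fir(x, c(2, 1, 0, -1, -2) / 8)
}

#' @rdname lowpass_filter
#' @export
square_signal <- function(x) {
  check_signal(x)
  x^2
}

#' @rdname lowpass_filter
#' @export
integrate_window <- function(x, window_samples) {
  check_signal(x)
  n <- as.integer(window_samples)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    abort("`window_samples` must be a single integer >= 1.")
  }
  if (n > length(x)) {
    abort("`window_samples` exceeds the signal length.")
  }
  cs <- cumsum(x)
  i <- seq_along(x)
  lag <- ifelse(i > n, cs[pmax(i - n, 1L)], 0)
  (cs - lag) / pmin(i, n)
}

# Causal FIR with zero history: x is zero-padded in front so the first
# outputs see only the available prefix, matching a zero-initial-state
# difference-equation recursion.
causal_fir <- function(x, b) {
  k <- length(b) - 1L
  y <- stats::filter(c(numeric(k), x), b, method = "convolution", sides = 1)
  as.numeric(y[(k + 1L):(k + length(x))])
}

check_signal <- function(x) {
  if (!is.numeric(x)) abort("signal must be numeric.")
  if (length(x) && !all(is.finite(x))) {
    abort("signal contains non-finite values (NA/NaN/Inf); clean it before filtering.")
  }
  invisible(x)
}

#' Run the full QRS conditioning chain on an ECG record
#'
#' Chains low-pass, high-pass, five-point derivative, squaring and
#' moving-window integration. The filter coefficients are the 200 Hz design;
#' in native-rate mode they are applied unchanged at the record's own
#' sampling rate (the band edges shift accordingly), while the integration
#' window always spans ~150 ms (`round(0.150 * fs)` samples, 30 at 200 Hz).
#' Use [resample_ecg_200hz()] first for rate-normalised analysis.
#'
#' @param record An [ecg_record()] tibble, or a bare numeric vector with `fs`
#'   supplied.
#' @param fs Sampling rate in Hz; taken from `record` when absent.
#' @return An `ecg_processed` tibble with columns `sample`, `bandpassed`,
#'   `derivative`, `integrated`, carrying attributes `fs`, `window_samples`
#'   and `stage_delays` (per-stage group delay in samples).
#' @examples
#' rec <- simulate_ecg(fs = 200, duration_s = 10, seed = 1)
#' proc <- preprocess_ecg(rec)
#' attr(proc, "window_samples")
#' @export
preprocess_ecg <- function(record, fs = NULL) {
  if (is.data.frame(record)) {
    fs <- fs %||% ecg_fs(record)
    x <- record$amplitude
    id <- ecg_id(record)
    ann <- ecg_annotations(record)
  } else {
    if (is.null(fs)) abort("`fs` is required when `record` is a bare vector.")
    x <- record
    id <- "record"
    ann <- NULL
  }
  check_signal(x)
  n_win <- max(1L, as.integer(round(0.150 * fs)))
  bp <- highpass_filter(lowpass_filter(x))
  dv <- derivative_filter(bp)
  integ <- integrate_window(square_signal(dv), n_win)
  out <- tibble(
    sample = seq_along(x) - 1L,
    bandpassed = bp,
    derivative = dv,
    integrated = integ
  )
  structure(
    out,
    fs = fs,
    record_id = id,
    annotations = ann,
    window_samples = n_win,
    stage_delays = c(lowpass = 6L, highpass = 16L, derivative = 2L,
                     integration = as.integer(floor(n_win / 2))),
    raw = as.numeric(x),
    class = c("ecg_processed", class(out))
  )
}

#' @export
print.ecg_processed <- function(x, ...) {
  cat(sprintf(
    "<ecg_processed> %s: %d samples @ %g Hz, integration window %d samples\n",
    attr(x, "record_id") %||% "record", nrow(x), attr(x, "fs"),
    attr(x, "window_samples")
  ))
  NextMethod()
}

#' Resample an ECG record to the 200 Hz filter design rate
#'
#' Polyphase FIR rational resampling (via [signal::resample()]) to 200 Hz, so
#' that every record is filtered with identical cut-off frequencies.
#' Annotation indices are mapped by `round(i * 200 / fs)`, preserving
#' annotation times to within half an output sample. A record already at
#' 200 Hz is returned unchanged.
#'
#' @param record An [ecg_record()] tibble.
#' @return An [ecg_record()] tibble at 200 Hz.
#' @export
resample_ecg_200hz <- function(record) {
  fs <- ecg_fs(record)
  if (fs == 200) {
    return(record)
  }
  frac <- ratio_int(200, fs)
  y <- resample_rational(record$amplitude, frac[1], frac[2])
  n_out <- length(y)
  ann <- ecg_annotations(record)
  idx <- as.integer(round(ann$sample * 200 / fs))
  keep <- idx >= 0L & idx < n_out
  ecg_record(y, fs = 200, record_id = ecg_id(record),
             annotations = tibble(sample = idx[keep], label = ann$label[keep]))
}

# Rational p/q resampling by zero-stuffing, linear-phase FIR anti-alias
# filtering (windowed sinc via signal::fir1) and decimation. The FIR length
# is odd, so its (L-1)/2 group delay is removed exactly: an impulse maps to
# round(i * p / q) with no residual shift.
resample_rational <- function(x, p, q) {
  n <- length(x)
  z <- numeric(n * p)
  z[seq(1L, length(z), by = p)] <- x
  l <- 2L * 10L * max(p, q) + 1L
  h <- p * signal::fir1(l - 1L, 1 / max(p, q))
  zf <- signal::fftfilt(h, c(z, numeric(l)))
  half <- (l - 1L) / 2L
  zf <- zf[(half + 1L):(half + n * p)]
  zf[seq(1L, n * p, by = q)]
}

# Reduce 200/fs to an integer ratio; non-integer rates are scaled up first.
ratio_int <- function(p, q) {
  scale <- 1
  while ((p * scale) %% 1 != 0 || (q * scale) %% 1 != 0) scale <- scale * 10
  p <- p * scale
  q <- q * scale
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
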