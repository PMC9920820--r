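#' Detect QRS complexes in a conditioned ECG signal
#'
#' A causal, deterministic state machine over the moving-window-integrated
#' signal. Two detector variants share one engine:
#'
#' * `detector = "ampt"` — the streamlined single-signal detector: adaptive
#'   signal/noise peak estimates on the integrated track only
#'   (`SPKF = 0.125 PEAKF + 0.875 SPKF`, likewise `NPKF`), thresholds
#'   `T1 = NPKF + 0.25 (SPKF - NPKF)` and `T2 = 0.25 T1`, a single averaged
#'   RR interval (mean of the last 8) whose 1.66x multiple triggers
#'   search-back at the lowered threshold `T2`, and search-back acceptances
#'   updating `SPKF` with the same 0.125/0.875 coefficients as normal beats.
#' * `detector = "pt"` — the original Pan-Tompkins: the same bookkeeping run
#'   simultaneously on the band-passed signal, a QRS accepted only when the
#'   integrated and band-passed peaks exceed both first thresholds within the
#'   integration-window latency; two RR averages (all beats, and beats whose
#'   RR fell inside the 92-116% regularity band) with threshold halving while
#'   the rhythm is irregular; search-back updates with the original 0.25/0.75
#'   coefficients.
#'
#' Both variants keep a 200 ms refractory period and the T-wave rule: a
#' candidate within 360 ms of the previous QRS whose maximal absolute
#' derivative-stage slope (within +/-75 ms) is less than half that of the
#' previous QRS is labelled a T wave and treated as noise.
#'
#' State is initialised from the first 2 s of signal (signal-peak estimate
#' 0.25x the maximum, noise-peak 0.5x the mean, the first ~0.5 s of filter
#' transient excluded) and detection starts after the transient. Accepted
#' peaks are mapped back to raw-signal coordinates by subtracting the chain
#' group delay and refining to the maximal absolute band-passed amplitude
#' within +/-75 ms.
#'
#' @param processed An `ecg_processed` tibble from [preprocess_ecg()], or an
#'   `ecg_tbl` (preprocessed on the fly).
#' @param fs Sampling rate in Hz; taken from `processed` when absent.
#' @param detector `"ampt"` (single-signal, default) or `"pt"` (original
#'   dual-signal Pan-Tompkins).
#' @param search_back Enable RR-missed-limit search-back (default `TRUE`).
#' @param twave_rule Enable T-wave discrimination (default `TRUE`).
#' @param dual_signal,dual_rr,searchback_coefs Structural overrides for the
#'   `"pt"` engine (defaults `TRUE`, `TRUE`, `c(0.25, 0.75)`). Setting
#'   `dual_signal = FALSE`, `dual_rr = FALSE`,
#'   `searchback_coefs = c(0.125, 0.875)` reduces the original detector to
#'   the streamlined one — the structural simplification made explicit.
#'   Ignored (fixed at the streamlined settings) for `"ampt"`.
#' @return A `qrs_detection` tibble with columns `sample` (0-based raw-signal
#'   index, strictly increasing) and `time_s`, carrying attributes
#'   `detector`, `record_id`, `fs`, `op_count` (tally of threshold-update and
#'   comparison operations, a hardware-independent efficiency proxy) and
#'   `peaks_integrated` (accepted peak indices in integrated-signal
#'   coordinates).
#' @examples
#' rec <- simulate_ecg(fs = 200, duration_s = 30, hr_bpm = 72, seed = 7)
#' det <- detect_qrs(preprocess_ecg(rec))
#' nrow(det)
#' @export
detect_qrs <- function(processed, fs = NULL, detector = c("ampt", "pt"),
                       search_back = TRUE, twave_rule = TRUE,
                       dual_signal = NULL, dual_rr = NULL,
                       searchback_coefs = NULL) {
  detector <- match.arg(detector)
  if (inherits(processed, "ecg_tbl") || (is.data.frame(processed) && "amplitude" %in% names(processed))) {
    processed <- preprocess_ecg(processed, fs = fs)
  }
  if (!inherits(processed, "ecg_processed")) {
    abort("`processed` must come from preprocess_ecg() or be an ecg_tbl.")
  }
  fs <- fs %||% ecg_fs(processed)
  if (detector == "ampt") {
    opts <- list(dual_signal = FALSE, dual_rr = FALSE,
                 searchback_coefs = c(0.125, 0.875))
  } else {
    opts <- list(
      dual_signal = dual_signal %||% TRUE,
      dual_rr = dual_rr %||% TRUE,
      searchback_coefs = searchback_coefs %||% c(0.25, 0.75)
    )
  }
  opts$search_back <- isTRUE(search_back)
  opts$twave_rule <- isTRUE(twave_rule)
  res <- qrs_engine(processed, fs, opts)
  out <- tibble(
    sample = as.integer(res$r_peaks - 1L),
    time_s = (res$r_peaks - 1L) / fs
  )
  structure(
    out,
    detector = detector,
    record_id = attr(processed, "record_id") %||% "record",
    fs = fs,
    op_count = res$op_count,
    peaks_integrated = as.integer(res$accepted - 1L),
    class = c("qrs_detection", class(out))
  )
}

#' @export
print.qrs_detection <- function(x, ...) {
  cat(sprintf(
    "<qrs_detection> %s via %s: %d beats @ %g Hz (op count %d)\n",
    attr(x, "record_id"), attr(x, "detector"), nrow(x), attr(x, "fs"),
    attr(x, "op_count")
  ))
  NextMethod()
}

# ---- adaptive threshold arithmetic (exported primitives) --------------------

#' Adaptive threshold primitives
#'
#' The exponentially weighted running estimates and decision thresholds of
#' the detector, exposed for inspection and testing. `update_signal_peak()`
#' and `update_noise_peak()` apply `0.125 * PEAKF + 0.875 * <estimate>`;
#' `compute_thresholds()` returns `T1 = NPKF + 0.25 (SPKF - NPKF)` and
#' `T2 = 0.25 T1`; `rr_stats()` returns the mean of the (up to 8 most
#' recent) RR intervals and the missed-beat limit `1.66 x` that mean.
#'
#' @param spkf,npkf Running signal/noise peak estimates (>= 0).
#' @param peakf Height of the current peak (>= 0).
#' @param rr_buffer Numeric vector of RR intervals in samples (most recent
#'   last; only the last 8 are used).
#' @return `update_*()` the new estimate; `compute_thresholds()` a named
#'   list `threshold_f1`, `threshold_f2`; `rr_stats()` a named list
#'   `rr_average1`, `rr_missed_limit`.
#' @export
update_signal_peak <- function(spkf, peakf) {
  check_level(spkf, "spkf")
  check_level(peakf, "peakf")
  0.125 * peakf + 0.875 * spkf
}

#' @rdname update_signal_peak
#' @export
update_noise_peak <- function(npkf, peakf) {
  check_level(npkf, "npkf")
  check_level(peakf, "peakf")
  0.125 * peakf + 0.875 * npkf
}

#' @rdname update_signal_peak
#' @export
compute_thresholds <- function(spkf, npkf) {
  t1 <- npkf + 0.25 * (spkf - npkf)
  list(threshold_f1 = t1, threshold_f2 = 0.25 * t1)
}

#' @rdname update_signal_peak
#' @export
rr_stats <- function(rr_buffer) {
  if (length(rr_buffer) == 0L) {
    abort("empty RR buffer: no RR average yet (search-back disabled).")
  }
  buf <- utils::tail(rr_buffer, 8L)
  avg <- mean(buf)
  list(rr_average1 = avg, rr_missed_limit = 1.66 * avg)
}

check_level <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name))
  }
}

# ---- engine -----------------------------------------------------------------

# Strict local maxima of z; a plateau counts once, at its first sample.
find_candidate_peaks <- function(z) {
  d <- diff(z)
  nz <- which(d != 0)
  if (length(nz) < 2L) {
    return(integer())
  }
  sgn <- d[nz]
  starts <- nz[-length(nz)]
  up_down <- sgn[-length(sgn)] > 0 & sgn[-1] < 0
  starts[up_down] + 1L
}

# A single QRS produces a ragged integrated hump with several strict local
# maxima; only the tallest within any refractory span is a candidate event
# (non-maximum suppression, ties to the earlier peak). Without this the
# hump's own shoulders would be booked as noise peaks taller than the
# accepted signal peak.
suppress_nearby_peaks <- function(idx, height, min_dist) {
  if (length(idx) < 2L) {
    return(idx)
  }
  ord <- order(-height, idx)
  blocked <- logical(length(idx))
  keep <- logical(length(idx))
  for (k in ord) {
    if (blocked[k]) next
    keep[k] <- TRUE
    blocked[abs(idx - idx[k]) < min_dist] <- TRUE
  }
  idx[keep]
}

qrs_engine <- function(processed, fs, opts) {
  z <- processed$integrated
  bp <- processed$bandpassed
  dv <- processed$derivative
  n <- length(z)
  n_learn <- as.integer(round(2 * fs))
  if (n < n_learn) {
    warn("record shorter than the 2 s learning phase: no detections.")
    return(list(r_peaks = integer(), accepted = integer(), op_count = 0L))
  }
  t_skip <- as.integer(round(0.5 * fs))
  learn <- (t_skip + 1L):n_learn

  refractory <- as.integer(round(0.200 * fs))
  twave_win <- as.integer(round(0.360 * fs))
  slope_win <- as.integer(round(0.075 * fs))
  latency <- attr(processed, "window_samples")

  abs_dv <- abs(dv)
  abs_bp <- abs(bp)
  # the integrated peak lags the derivative-stage energy by roughly half the
  # integration window; centre the slope measurement there
  integ_off <- as.integer(attr(processed, "stage_delays")[["integration"]])
  slope_at <- function(p) {
    c0 <- max(1L, p - integ_off)
    max(abs_dv[max(1L, c0 - slope_win):min(n, c0 + slope_win)])
  }

  peaks <- find_candidate_peaks(z)
  peaks <- suppress_nearby_peaks(peaks, z[peaks], refractory)
  peaks <- peaks[peaks > t_skip]
  np <- length(peaks)
  # band-passed companion peak: max |bp| within the integration latency
  # preceding each integrated peak (dual-signal mode only)
  if (opts$dual_signal && np > 0) {
    bp_peak <- vapply(peaks, function(p) {
      max(abs_bp[max(1L, p - latency):p])
    }, numeric(1))
  } else {
    bp_peak <- numeric(np)
  }

  spk <- 0.25 * max(z[learn])
  npk <- 0.5 * mean(z[learn])
  thr <- compute_thresholds(spk, npk)
  if (opts$dual_signal) {
    spk_b <- 0.25 * max(abs_bp[learn])
    npk_b <- 0.5 * mean(abs_bp[learn])
    thr_b <- compute_thresholds(spk_b, npk_b)
  }
  irregular <- FALSE
  thr1 <- function() thr$threshold_f1 * if (opts$dual_rr && irregular) 0.5 else 1
  thr2 <- function() thr$threshold_f2 * if (opts$dual_rr && irregular) 0.5 else 1
  thr1_b <- function() thr_b$threshold_f1 * if (opts$dual_rr && irregular) 0.5 else 1
  thr2_b <- function() thr_b$threshold_f2 * if (opts$dual_rr && irregular) 0.5 else 1

  last_qrs <- NA_integer_
  last_slope <- NA_real_
  rr1 <- numeric()
  rr2 <- numeric()
  accepted <- integer(0)
  ops <- 0L

  push_rr <- function(rr) {
    rr1 <<- utils::tail(c(rr1, rr), 8L)
    ops <<- ops + 1L
    if (opts$dual_rr) {
      # regularity band 92-116% of the selective average; until that average
      # exists every RR is taken as regular
      if (length(rr2) == 0L) {
        rr2 <<- rr
        irregular <<- FALSE
      } else {
        avg2 <- mean(rr2)
        ops <<- ops + 3L  # avg + two band comparisons
        if (rr >= 0.92 * avg2 && rr <= 1.16 * avg2) {
          rr2 <<- utils::tail(c(rr2, rr), 8L)
          irregular <<- FALSE
        } else {
          irregular <<- TRUE
        }
      }
    }
  }

  note_noise <- function(i) {
    npk <<- update_noise_peak(npk, z[peaks[i]])
    thr <<- compute_thresholds(spk, npk)
    ops <<- ops + 3L
    if (opts$dual_signal) {
      npk_b <<- update_noise_peak(npk_b, bp_peak[i])
      thr_b <<- compute_thresholds(spk_b, npk_b)
      ops <<- ops + 3L
    }
  }

  accept_qrs <- function(i, coefs) {
    p <- peaks[i]
    spk <<- coefs[1] * z[p] + coefs[2] * spk
    thr <<- compute_thresholds(spk, npk)
    ops <<- ops + 3L
    if (opts$dual_signal) {
      spk_b <<- coefs[1] * bp_peak[i] + coefs[2] * spk_b
      thr_b <<- compute_thresholds(spk_b, npk_b)
      ops <<- ops + 3L
    }
    if (!is.na(last_qrs)) push_rr(p - last_qrs)
    last_qrs <<- p
    last_slope <<- slope_at(p)
    accepted <<- c(accepted, p)
  }

  is_twave <- function(i) {
    if (!opts$twave_rule || is.na(last_qrs)) {
      return(FALSE)
    }
    p <- peaks[i]
    ops <<- ops + 1L
    if (p - last_qrs >= twave_win) {
      return(FALSE)
    }
    ops <<- ops + 1L
    slope_at(p) < 0.5 * last_slope
  }

  try_search_back <- function(i) {
    # triggered when the gap to the current candidate exceeds the missed limit
    repeat {
      if (!opts$search_back || length(rr1) < 2L || is.na(last_qrs)) break
      missed <- if (opts$dual_rr && length(rr2) > 0L) {
        ops <<- ops + 2L
        1.66 * mean(rr2)
      } else {
        ops <<- ops + 2L
        1.66 * mean(rr1)
      }
      ops <<- ops + 1L
      if (peaks[i] - last_qrs <= missed) break
      lo <- last_qrs + refractory
      hi <- peaks[i]
      cand <- which(peaks > lo & peaks < hi)
      ok <- logical(length(cand))
      for (k in seq_along(cand)) {
        j <- cand[k]
        ops <<- ops + 1L
        pass <- z[peaks[j]] > thr2()
        if (pass && opts$dual_signal) {
          ops <<- ops + 1L
          pass <- bp_peak[j] > thr2_b()
        }
        if (pass && opts$twave_rule && (peaks[j] - last_qrs) < twave_win) {
          ops <<- ops + 2L
          pass <- slope_at(peaks[j]) >= 0.5 * last_slope
        }
        ok[k] <- pass
      }
      cand <- cand[ok]
      if (length(cand) == 0L) break
      best <- cand[which.max(z[peaks[cand]])]  # tallest; which.max ties -> earliest
      accept_qrs(best, opts$searchback_coefs)
    }
  }

  for (i in seq_len(np)) {
    p <- peaks[i]
    if (!is.na(last_qrs)) try_search_back(i)
    if (!is.na(last_qrs) && p <= last_qrs) next  # consumed by search-back bookkeeping
    if (!is.na(last_qrs)) {
      ops <- ops + 1L
      if (p - last_qrs < refractory) {
        note_noise(i)
        next
      }
    }
    ops <- ops + 1L
    above <- z[p] > thr1()
    if (above && opts$dual_signal) {
      ops <- ops + 1L
      above <- bp_peak[i] > thr1_b()
    }
    if (above) {
      if (is_twave(i)) {
        note_noise(i)
      } else {
        accept_qrs(i, c(0.125, 0.875))
      }
    } else {
      note_noise(i)
    }
  }

  delays <- attr(processed, "stage_delays")
  raw <- map_peaks_to_raw(accepted, delays, bp, fs, raw_signal = attr(processed, "raw"))
  # refractory holds in integrated coordinates; re-impose it after the
  # +/-75 ms raw refinement so the output contract is unconditional
  if (length(raw) > 1L) {
    keep <- c(TRUE, diff(raw) >= refractory)
    raw <- raw[keep]
  }
  list(r_peaks = raw, accepted = accepted, op_count = ops)
}

#' Map integrated-signal peak indices to raw-signal coordinates
#'
#' Subtracts the total conditioning-chain group delay, then refines each
#' index to the maximal absolute band-passed amplitude within +/-75 ms
#' (the band-passed track being searched at its own low+high-pass delay).
#' Results are clipped to the record bounds.
#'
#' @param peaks Integer vector of 0-based integrated-track peak indices.
#' @param stage_delays Named delays as stored on an `ecg_processed` object.
#' @param bandpassed Band-passed signal track.
#' @param fs Sampling rate in Hz.
#' @param raw_signal Optional raw samples; when given, each peak is further
#'   snapped to the largest absolute deviation from the local median within
#'   +/-25 ms, pinning it to the R apex.
#' @return Integer vector of 0-based raw-signal indices.
#' @export
map_peak_to_raw <- function(peaks, stage_delays, bandpassed, fs, raw_signal = NULL) {
  as.integer(map_peaks_to_raw(as.integer(peaks) + 1L, stage_delays, bandpassed, fs,
                              raw_signal = raw_signal) - 1L)
}

map_peaks_to_raw <- function(peaks1, delays, bp, fs, raw_signal = NULL) {
  if (length(peaks1) == 0L) {
    return(integer())
  }
  n <- length(bp)
  total <- sum(delays)
  # exact group delay of the band-pass pair: the low-pass section delays by
  # 5 samples and the high-pass by ~15, two less than the nominal 6 + 16
  # bookkeeping; using the exact value keeps refined peaks on the R apex
  bp_delay <- as.integer(delays[["lowpass"]] + delays[["highpass"]]) - 2L
  win <- as.integer(round(0.075 * fs))
  abs_bp <- abs(bp)
  apex_win <- as.integer(round(0.025 * fs))
  base_win <- as.integer(round(0.150 * fs))
  out <- vapply(peaks1, function(p) {
    est <- p - total
    centre <- min(max(est + bp_delay, 1L), n)
    lo <- max(1L, centre - win)
    hi <- min(n, centre + win)
    j <- lo + which.max(abs_bp[lo:hi]) - 1L
    loc <- min(max(j - bp_delay, 1L), n)
    if (!is.null(raw_signal)) {
      # baseline from a wide window (median is insensitive to the QRS
      # itself), apex search in a narrow one
      blo <- max(1L, loc - base_win)
      bhi <- min(n, loc + base_win)
      baseline <- stats::median(raw_signal[blo:bhi])
      rlo <- max(1L, loc - apex_win)
      rhi <- min(n, loc + apex_win)
      seg <- raw_signal[rlo:rhi]
      loc <- rlo + which.max(abs(seg - baseline)) - 1L
    }
    loc
  }, numeric(1))
  as.integer(out)
}
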