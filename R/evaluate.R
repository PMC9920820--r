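#' Match detected beats against reference annotations
#'
#' One-to-one beat-by-beat pairing with a fixed temporal tolerance (150 ms by
#' default, the ANSI/AAMI convention). Annotations are processed in order;
#' each is paired greedily with the nearest unmatched detection within the
#' tolerance, ties going to the earlier detection. Unmatched detections are
#' false positives, unmatched annotations false negatives.
#'
#' @param detected A `qrs_detection` tibble, a data frame with a `sample`
#'   column, or a strictly increasing numeric vector of detection indices.
#' @param annotated Reference beats: an annotation tibble (`sample` column),
#'   an `ecg_tbl` (its annotations are used), or a strictly increasing
#'   numeric vector.
#' @param fs Sampling rate in Hz (used to convert the tolerance).
#' @param tolerance_ms Matching window in milliseconds (default 150).
#' @return A `beat_match` object: list with `pairs` (tibble of
#'   `annotation`, `detection`, `delta_samples`), counts `tp`, `fp`, `fn`,
#'   `tb`, and the inputs' metadata. `tp + fn == tb` always holds.
#' @examples
#' m <- match_beats(c(100, 300, 520), c(100, 300, 500), fs = 200)
#' glance(m)
#' @export
match_beats <- function(detected, annotated, fs, tolerance_ms = 150) {
  det <- extract_indices(detected)
  ann <- extract_indices(annotated)
  if (is.unsorted(det, strictly = TRUE)) abort("`detected` indices must be strictly increasing.")
  if (is.unsorted(ann, strictly = TRUE)) abort("`annotated` indices must be strictly increasing.")
  tol <- tolerance_ms / 1000 * fs
  used <- logical(length(det))
  pairs_a <- integer(0)
  pairs_d <- integer(0)
  for (i in seq_along(ann)) {
    free <- which(!used)
    if (length(free) == 0L) break
    dist <- abs(det[free] - ann[i])
    ok <- dist <= tol
    if (!any(ok)) next
    # nearest; ties -> earlier detection (which.min already takes the first,
    # and `free` is in increasing detection order)
    j <- free[ok][which.min(dist[ok])]
    used[j] <- TRUE
    pairs_a <- c(pairs_a, i)
    pairs_d <- c(pairs_d, j)
  }
  tp <- length(pairs_a)
  structure(
    list(
      pairs = tibble(
        annotation = ann[pairs_a],
        detection = det[pairs_d],
        delta_samples = det[pairs_d] - ann[pairs_a]
      ),
      tp = tp,
      fp = length(det) - tp,
      fn = length(ann) - tp,
      tb = length(ann),
      fs = fs,
      tolerance_ms = tolerance_ms,
      record_id = attr(detected, "record_id") %||% "record",
      detector = attr(detected, "detector") %||% NA_character_
    ),
    class = "beat_match"
  )
}

extract_indices <- function(x) {
  if (inherits(x, "ecg_tbl")) {
    return(as.numeric(ecg_annotations(x)$sample))
  }
  if (is.data.frame(x)) {
    if (!"sample" %in% names(x)) abort("data frame input needs a `sample` column.")
    return(as.numeric(x$sample))
  }
  as.numeric(x)
}

#' @export
print.beat_match <- function(x, ...) {
  cat(sprintf(
    "<beat_match> %s: TP %d, FP %d, FN %d of %d annotated beats (tol %g ms)\n",
    x$record_id, x$tp, x$fp, x$fn, x$tb, x$tolerance_ms
  ))
  invisible(x)
}

#' Assemble detection counts without a matching run
#'
#' For desk-scale arithmetic on counts reported elsewhere (published
#' benchmark tables, external scorers). The resulting object feeds the same
#' metric functions as [match_beats()]. Note `tb` is taken as given and is
#' not forced to equal `tp + fn`; published tables are sometimes internally
#' inconsistent and the error-rate definition divides by the printed total.
#'
#' @param tp,fp,fn True positives, false positives, false negatives.
#' @param tb Total annotated beats (defaults to `tp + fn`).
#' @param record_id Optional label.
#' @return A `beat_match` object (without pair detail).
#' @export
beat_counts <- function(tp, fp, fn, tb = tp + fn, record_id = "counts") {
  structure(
    list(pairs = NULL, tp = tp, fp = fp, fn = fn, tb = tb,
         fs = NA_real_, tolerance_ms = NA_real_,
         record_id = record_id, detector = NA_character_),
    class = "beat_match"
  )
}

#' Beat-detection correctness metrics
#'
#' The standard QRS-detection correctness measures, each as a percentage:
#' total error rate `100 (FN + FP) / TB`, sensitivity `100 TP / (TP + FN)`,
#' positive predictive value `100 TP / (TP + FP)`, accuracy
#' `100 TP / (TP + FP + FN)` and `F1 = 100 * 2 TP / (2 TP + FP + FN)`.
#' `failed_detection()` is the combined count `FP + FN`. Undefined ratios
#' (zero denominator) return `NA` with a warning.
#'
#' @param m A `beat_match` from [match_beats()] or [beat_counts()].
#' @return A single number (percentage, except `failed_detection()`: a count).
#' @export
total_error_rate <- function(m) safe_pct(m$fn + m$fp, m$tb, "total error rate")

#' @rdname total_error_rate
#' @export
sensitivity <- function(m) safe_pct(m$tp, m$tp + m$fn, "sensitivity")

#' @rdname total_error_rate
#' @export
ppv <- function(m) safe_pct(m$tp, m$tp + m$fp, "positive predictive value")

#' @rdname total_error_rate
#' @export
accuracy <- function(m) safe_pct(m$tp, m$tp + m$fp + m$fn, "accuracy")

#' @rdname total_error_rate
#' @export
f1_score <- function(m) safe_pct(2 * m$tp, 2 * m$tp + m$fp + m$fn, "F1")

#' @rdname total_error_rate
#' @export
failed_detection <- function(m) m$fp + m$fn

safe_pct <- function(num, den, what) {
  if (is.na(den) || den == 0) {
    warn(sprintf("%s undefined: zero denominator.", what))
    return(NA_real_)
  }
  100 * num / den
}

#' One-row metrics table for a matched record
#'
#' @param m A `beat_match`.
#' @return A one-row tibble with the counts and all five percentage metrics.
#' @export
qrs_metrics <- function(m) {
  tibble(
    record_id = m$record_id,
    detector = m$detector,
    tp = m$tp, fp = m$fp, fn = m$fn, tb = m$tb,
    failed_detection = failed_detection(m),
    total_error_rate = total_error_rate(m),
    sensitivity = sensitivity(m),
    ppv = ppv(m),
    accuracy = accuracy(m),
    f1 = f1_score(m)
  )
}

#' @exportS3Method generics::glance
glance.beat_match <- function(x, ...) qrs_metrics(x)

#' @exportS3Method generics::tidy
tidy.beat_match <- function(x, ...) {
  if (is.null(x$pairs)) {
    return(tibble(annotation = numeric(), detection = numeric(), delta_samples = numeric()))
  }
  x$pairs
}

#' Aggregate per-record metrics across a dataset
#'
#' Two aggregation bases, both reported: `pooled` sums TP/FP/FN/TB across
#' records and applies the metric definitions to the pooled counts;
#' `per_record_mean` averages the per-record percentages. The two differ
#' whenever record sizes or error profiles are unbalanced.
#'
#' @param matches A list of `beat_match` objects (or a single one).
#' @return A tibble with one row per basis, columns as [qrs_metrics()] plus
#'   `basis` and `n_records`.
#' @export
aggregate_metrics <- function(matches) {
  if (inherits(matches, "beat_match")) matches <- list(matches)
  if (length(matches) == 0L) abort("no match results to aggregate.")
  per <- bind_rows(lapply(matches, qrs_metrics))
  pooled <- beat_counts(sum(per$tp), sum(per$fp), sum(per$fn), sum(per$tb),
                        record_id = "pooled")
  pooled_row <- qrs_metrics(pooled)
  pooled_row$basis <- "pooled"
  mean_row <- tibble(
    record_id = "mean", detector = per$detector[1],
    tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn), tb = sum(per$tb),
    failed_detection = sum(per$failed_detection),
    total_error_rate = mean(per$total_error_rate),
    sensitivity = mean(per$sensitivity),
    ppv = mean(per$ppv),
    accuracy = mean(per$accuracy),
    f1 = mean(per$f1),
    basis = "per_record_mean"
  )
  pooled_row$detector <- per$detector[1]
  out <- bind_rows(pooled_row, mean_row)
  out$n_records <- nrow(per)
  out
}
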