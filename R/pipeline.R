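#' Load an ECG record from WFDB or CSV with dataset inclusion rules
#'
#' Dispatches on extension (`.hea`/bare prefix: WFDB; `.csv`: CSV time
#' series), selects the first-listed lead of multi-channel records, filters
#' annotations to beat classes, and optionally truncates record and
#' annotations jointly to the first `max_minutes` (half-open interval
#' `[0, max_minutes * 60 * fs)`).
#'
#' @param path Record path (`.hea`, WFDB prefix, or `.csv`).
#' @param fs Sampling rate (CSV with a `sample` column only).
#' @param max_minutes Truncation limit in minutes; `NULL` keeps everything.
#' @param channel 1-based channel for multi-lead WFDB records (default: first
#'   listed).
#' @param annotations Optional annotations for CSV inputs.
#' @return An [ecg_record()] tibble.
#' @export
load_record <- function(path, fs = NULL, max_minutes = NULL, channel = 1L,
                        annotations = NULL) {
  rec <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read_ecg_csv(path, fs = fs, annotations = annotations)
  } else {
    read_wfdb(path, channel = channel)
  }
  ann <- beat_annotations(ecg_annotations(rec))
  if (!is.null(max_minutes)) {
    if (max_minutes <= 0) abort("`max_minutes` must be > 0.")
    n_keep <- as.integer(floor(max_minutes * 60 * ecg_fs(rec)))
    if (n_keep < nrow(rec)) {
      keep_amp <- rec$amplitude[seq_len(n_keep)]
      ann <- ann[ann$sample < n_keep, , drop = FALSE]
      return(ecg_record(keep_amp, fs = ecg_fs(rec), record_id = ecg_id(rec),
                        annotations = ann))
    }
  }
  ecg_record(rec$amplitude, fs = ecg_fs(rec), record_id = ecg_id(rec),
             annotations = ann)
}

#' Run detection and evaluation over a dataset manifest
#'
#' The end-to-end benchmark: each manifest entry is loaded, optionally
#' resampled to 200 Hz, conditioned, run through the chosen detector and
#' scored beat-by-beat against its annotations. Per-record failures are
#' logged and skipped; the run continues.
#'
#' @param manifest A data frame with a `path` column (optional: `record_id`,
#'   `label`, `fs`, `max_minutes`), or a character vector of paths. Records
#'   listed in an optional `exclude` logical column are dropped.
#' @param detector `"ampt"` or `"pt"`.
#' @param mode `"native"` (filters run at the record's own rate) or
#'   `"resample200"` (records resampled to the 200 Hz design rate first).
#' @param tolerance_ms Matching window (default 150 ms).
#' @param max_minutes Global truncation limit, overridden per record by a
#'   manifest column of the same name.
#' @param search_back,twave_rule Passed to [detect_qrs()].
#' @return A `qrs_benchmark` object: list with `per_record` (one metrics row
#'   per record), `aggregate` (both aggregation bases), `detections` (list of
#'   `qrs_detection`), `op_counts`, `failures` (character vector of failed
#'   paths), `detector`, `mode`.
#' @export
run_pipeline <- function(manifest, detector = c("ampt", "pt"),
                         mode = c("native", "resample200"),
                         tolerance_ms = 150, max_minutes = NULL,
                         search_back = TRUE, twave_rule = TRUE) {
  detector <- match.arg(detector)
  mode <- match.arg(mode)
  if (is.character(manifest)) manifest <- tibble(path = manifest)
  if (!is.data.frame(manifest) || !"path" %in% names(manifest) || nrow(manifest) == 0L) {
    abort("`manifest` must be a non-empty data frame with a `path` column.")
  }
  if ("exclude" %in% names(manifest)) {
    manifest <- manifest[!isTRUE_vec(manifest$exclude), , drop = FALSE]
  }
  matches <- list()
  detections <- list()
  ops <- integer(0)
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    res <- tryCatch({
      mm <- if ("max_minutes" %in% names(manifest) && !is.na(manifest$max_minutes[i])) {
        manifest$max_minutes[i]
      } else {
        max_minutes
      }
      rec <- load_record(p, fs = manifest$fs[i] %0% NULL, max_minutes = mm)
      if (mode == "resample200") rec <- resample_ecg_200hz(rec)
      det <- detect_qrs(preprocess_ecg(rec), detector = detector,
                        search_back = search_back, twave_rule = twave_rule)
      m <- match_beats(det, rec, fs = ecg_fs(rec), tolerance_ms = tolerance_ms)
      list(match = m, det = det)
    }, error = function(e) {
      warn(sprintf("record %s failed: %s", p, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      failures <- c(failures, p)
      next
    }
    matches[[length(matches) + 1L]] <- res$match
    detections[[length(detections) + 1L]] <- res$det
    ops <- c(ops, attr(res$det, "op_count"))
  }
  if (length(matches) == 0L) abort("no record in the manifest could be processed.")
  per <- bind_rows(lapply(matches, qrs_metrics))
  per$op_count <- ops
  structure(
    list(
      per_record = per,
      aggregate = aggregate_metrics(matches),
      detections = detections,
      op_counts = ops,
      failures = failures,
      detector = detector,
      mode = mode,
      tolerance_ms = tolerance_ms
    ),
    class = "qrs_benchmark"
  )
}

`%0%` <- function(x, y) if (is.null(x) || length(x) == 0L || all(is.na(x))) y else x

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.qrs_benchmark <- function(x, ...) {
  agg <- x$aggregate[x$aggregate$basis == "pooled", ]
  cat(sprintf(
    "<qrs_benchmark> %s (%s): %d record(s), pooled error rate %.2f%%, sensitivity %.2f%%, PPV %.2f%%\n",
    x$detector, x$mode, nrow(x$per_record),
    agg$total_error_rate, agg$sensitivity, agg$ppv
  ))
  if (length(x$failures)) {
    cat(sprintf("  %d record(s) failed: %s\n", length(x$failures),
                paste(x$failures, collapse = ", ")))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.qrs_benchmark <- function(x, ...) {
  out <- x$aggregate
  out$detector <- x$detector
  out$mode <- x$mode
  out$total_op_count <- sum(x$op_counts)
  out
}

#' @exportS3Method generics::tidy
tidy.qrs_benchmark <- function(x, ...) x$per_record

#' Write a benchmark report to CSV or JSON
#'
#' One row per record plus the two aggregate rows, with the count and metric
#' columns of a standard beat-by-beat scoring table. Percentages are rounded
#' to 2 decimal places in the file; the in-memory objects keep full
#' precision.
#'
#' @param benchmark A `qrs_benchmark` from [run_pipeline()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(benchmark, path, format = c("csv", "json")) {
  format <- match.arg(format)
  per <- benchmark$per_record
  per$basis <- "record"
  agg <- benchmark$aggregate
  agg$op_count <- NA_integer_
  tab <- bind_rows(per, agg[, intersect(names(per), names(agg))])
  pct_cols <- c("total_error_rate", "sensitivity", "ppv", "accuracy", "f1")
  tab[pct_cols] <- lapply(tab[pct_cols], round, digits = 2)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null", digits = NA)
  }
  invisible(path)
}
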