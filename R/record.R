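#' Construct an annotated single-lead ECG record
#'
#' An `ecg_tbl` is a tibble with columns `sample` (0-based index), `time_s`
#' and `amplitude`, carrying the sampling frequency, a record identifier and
#' an optional beat-annotation table as attributes. It is the common currency
#' of the package: the signal-conditioning chain, both detectors, the
#' evaluator and the writers all accept it.
#'
#' @param amplitude Numeric vector of samples (arbitrary units; finite).
#' @param fs Sampling frequency in Hz (> 0).
#' @param record_id Opaque record label.
#' @param annotations Optional annotations: an integer vector of 0-based
#'   R-peak sample indices, or a data frame with columns `sample` and
#'   (optionally) `label`. Indices must be strictly increasing and within
#'   `[0, length(amplitude))`.
#' @return A tibble of class `ecg_tbl` with columns `sample`, `time_s`,
#'   `amplitude`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 2, by = 1 / 200)), fs = 200)
#' ecg_fs(rec)
#' @export
ecg_record <- function(amplitude, fs, record_id = "record", annotations = NULL) {
  if (!is.numeric(amplitude) || length(amplitude) == 0L) {
    abort("`amplitude` must be a non-empty numeric vector.")
  }
  if (!all(is.finite(amplitude))) {
    abort("`amplitude` contains non-finite values; clean the signal before use.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  ann <- normalize_annotations(annotations, n = length(amplitude))
  out <- tibble(
    sample = seq_along(amplitude) - 1L,
    time_s = (seq_along(amplitude) - 1L) / fs,
    amplitude = as.numeric(amplitude)
  )
  structure(
    out,
    fs = fs,
    record_id = as.character(record_id),
    annotations = ann,
    class = c("ecg_tbl", class(out))
  )
}

normalize_annotations <- function(annotations, n) {
  if (is.null(annotations)) {
    return(tibble(sample = integer(), label = character()))
  }
  if (is.data.frame(annotations)) {
    if (!"sample" %in% names(annotations)) {
      abort("annotation data frame needs a `sample` column.")
    }
    idx <- as.integer(annotations$sample)
    lab <- if ("label" %in% names(annotations)) as.character(annotations$label) else rep("N", length(idx))
  } else {
    idx <- as.integer(annotations)
    lab <- rep("N", length(idx))
  }
  if (length(idx) > 0) {
    if (any(idx < 0L) || any(idx >= n)) {
      abort("annotation sample indices must lie within [0, record length).")
    }
    if (any(diff(idx) <= 0L)) {
      abort("annotation sample indices must be strictly increasing.")
    }
  }
  tibble(sample = idx, label = lab)
}

#' Accessors for ECG record metadata
#'
#' @param x An `ecg_tbl` (or an `ecg_processed` for `ecg_fs()`).
#' @return `ecg_fs()` the sampling rate in Hz; `ecg_annotations()` the
#'   annotation tibble (`sample`, `label`); `ecg_id()` the record label.
#' @export
ecg_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("object carries no `fs` attribute; pass `fs` explicitly.")
  fs
}

#' @rdname ecg_fs
#' @export
ecg_annotations <- function(x) {
  attr(x, "annotations") %||% tibble(sample = integer(), label = character())
}

#' @rdname ecg_fs
#' @export
ecg_id <- function(x) attr(x, "record_id") %||% "record"

#' @export
print.ecg_tbl <- function(x, ...) {
  fs <- attr(x, "fs")
  ann <- ecg_annotations(x)
  cat(sprintf(
    "<ecg_tbl> %s: %d samples @ %g Hz (%.1f s), %d annotated beats\n",
    ecg_id(x), nrow(x), fs, nrow(x) / fs, nrow(ann)
  ))
  NextMethod()
}

# Filter an annotation table to beat classes only. WFDB uses single-character
# codes; anything in `beat_labels` counts as a beat, the rest (rhythm changes,
# artifact marks, comments) is dropped before scoring.
beat_annotations <- function(ann, beat_labels = c(
                               "N", "L", "R", "B", "A", "a", "J", "S", "V",
                               "r", "F", "e", "j", "n", "E", "/", "f", "Q", "?"
                             )) {
  ann[ann$label %in% beat_labels, , drop = FALSE]
}

#' Read an ECG record from a two-column CSV time series
#'
#' Accepts `time_s,amplitude` or `sample,amplitude` columns, with or without a
#' header line. When the first column is a time in seconds the sampling rate is
#' inferred from the median spacing unless `fs` is given.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz; required when the file has a `sample` column,
#'   otherwise inferred from the time column if omitted.
#' @param record_id Record label; defaults to the file name.
#' @param annotations Optional annotations passed to [ecg_record()].
#' @return An [ecg_record()] tibble.
#' @export
read_ecg_csv <- function(path, fs = NULL, record_id = NULL, annotations = NULL) {
  if (!file.exists(path)) abort(sprintf("CSV record not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort(sprintf("expected two columns in %s", path))
  names(df)[1:2] <- if (has_header) tolower(names(df)[1:2]) else c("v1", "v2")
  xcol <- df[[1]]
  amp <- as.numeric(df[[2]])
  is_time <- if (has_header) names(df)[1] %in% c("time_s", "time", "t") else any(xcol %% 1 != 0)
  if (is.null(fs)) {
    if (!is_time) abort(sprintf("`fs` is required for sample-indexed CSV %s", path))
    fs <- 1 / stats::median(diff(as.numeric(xcol)))
  }
  ecg_record(amp, fs = fs,
             record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)),
             annotations = annotations)
}

#' Write an ECG record (and its annotations) as CSV
#'
#' @param record An `ecg_tbl`.
#' @param path Output CSV path; annotations, if any, go to
#'   `<path-sans-ext>_annotations.csv` with columns
#'   `record_id,sample,time_s,label`.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  utils::write.csv(
    data.frame(time_s = record$time_s, amplitude = record$amplitude),
    path,
    row.names = FALSE
  )
  ann <- ecg_annotations(record)
  if (nrow(ann) > 0) {
    apath <- paste0(sub("\\.[^.]*$", "", path), "_annotations.csv")
    utils::write.csv(
      data.frame(record_id = ecg_id(record), sample = ann$sample,
                 time_s = ann$sample / ecg_fs(record), label = ann$label),
      apath,
      row.names = FALSE
    )
  }
  invisible(path)
}
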