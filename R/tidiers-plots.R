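#' @exportS3Method generics::glance
glance.qrs_detection <- function(x, ...) {
  rr <- diff(x$time_s)
  tibble(
    record_id = attr(x, "record_id"),
    detector = attr(x, "detector"),
    n_beats = nrow(x),
    mean_hr_bpm = if (length(rr)) 60 / mean(rr) else NA_real_,
    mean_rr_s = if (length(rr)) mean(rr) else NA_real_,
    op_count = attr(x, "op_count")
  )
}

#' @exportS3Method generics::tidy
tidy.qrs_detection <- function(x, ...) as_tibble(x)

#' Plot an ECG record with its annotations
#'
#' @param object An `ecg_tbl`.
#' @param window_s Optional length-2 time window (seconds) to restrict the
#'   plot.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ecg_tbl <- function(object, window_s = NULL, ...) {
  df <- as_tibble(object)
  ann <- ecg_annotations(object)
  fs <- ecg_fs(object)
  if (!is.null(window_s)) {
    df <- df[df$time_s >= window_s[1] & df$time_s <= window_s[2], ]
    ann <- ann[ann$sample / fs >= window_s[1] & ann$sample / fs <= window_s[2], ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)", title = ecg_id(object)) +
    ggplot2::theme_minimal()
  if (nrow(ann)) {
    p <- p + ggplot2::geom_vline(
      xintercept = ann$sample / fs,
      colour = "firebrick", alpha = 0.35, linetype = "dashed"
    )
  }
  p
}

#' Plot the conditioning-chain stages
#'
#' @param object An `ecg_processed` tibble.
#' @param window_s Optional length-2 time window (seconds).
#' @param ... Unused.
#' @return A ggplot facetted by stage.
#' @exportS3Method ggplot2::autoplot
autoplot.ecg_processed <- function(object, window_s = NULL, ...) {
  fs <- ecg_fs(object)
  df <- tidyr::pivot_longer(
    mutate(as_tibble(object), time_s = .data$sample / fs),
    c("bandpassed", "derivative", "integrated"),
    names_to = "stage", values_to = "value"
  )
  df$stage <- factor(df$stage, levels = c("bandpassed", "derivative", "integrated"))
  if (!is.null(window_s)) {
    df <- df[df$time_s >= window_s[1] & df$time_s <= window_s[2], ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot detections over the raw signal
#'
#' @param object A `qrs_detection`.
#' @param record The `ecg_tbl` the detection came from (optional; detections
#'   alone are shown as a tick raster otherwise).
#' @param window_s Optional length-2 time window (seconds).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qrs_detection <- function(object, record = NULL, window_s = NULL, ...) {
  det <- as_tibble(object)
  if (!is.null(window_s)) det <- det[det$time_s >= window_s[1] & det$time_s <= window_s[2], ]
  if (is.null(record)) {
    return(
      ggplot2::ggplot(det, ggplot2::aes(x = .data$time_s)) +
        ggplot2::geom_vline(ggplot2::aes(xintercept = .data$time_s), colour = "steelblue") +
        ggplot2::labs(x = "time (s)", title = sprintf("%s detections", attr(object, "detector"))) +
        ggplot2::theme_minimal()
    )
  }
  autoplot.ecg_tbl(record, window_s = window_s) +
    ggplot2::geom_vline(
      data = det, ggplot2::aes(xintercept = .data$time_s),
      colour = "steelblue", alpha = 0.6
    )
}

#' Plot beat-matching residuals
#'
#' Histogram of detection-minus-annotation offsets (milliseconds) for the
#' matched pairs, with the matching tolerance marked.
#'
#' @param object A `beat_match`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.beat_match <- function(object, ...) {
  if (is.null(object$pairs) || nrow(object$pairs) == 0L) {
    abort("no matched pairs to plot.")
  }
  df <- mutate(object$pairs, delta_ms = .data$delta_samples / object$fs * 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_ms)) +
    ggplot2::geom_histogram(binwidth = 5, fill = "grey40") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$tolerance_ms,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "detection - annotation (ms)", y = "beats",
      title = sprintf("%s: TP %d, FP %d, FN %d", object$record_id,
                      object$tp, object$fp, object$fn)
    ) +
    ggplot2::theme_minimal()
}

#' Compare per-record metrics of two benchmark runs
#'
#' @param benchmarks Named list of `qrs_benchmark` objects (names become the
#'   legend, e.g. `list(ampt = ..., pt = ...)`).
#' @param metric Metric column to compare (default `"f1"`).
#' @return A ggplot bar chart, one bar group per record.
#' @export
plot_benchmark_comparison <- function(benchmarks, metric = "f1") {
  df <- bind_rows(imap(benchmarks, function(b, nm) {
    out <- b$per_record
    out$run <- nm
    out
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$record_id, y = .data[[metric]], fill = .data$run)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = sprintf("%s (%%)", metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
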