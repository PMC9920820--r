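#' Published benchmark detection counts
#'
#' Beat-by-beat detection counts reported for the original Pan-Tompkins
#' (`pt`) and the streamlined single-signal detector (`ampt`) on six groups
#' of public annotated ECG datasets (high/low signal quality, normal sinus
#' rhythm, arrhythmias, paced rhythm, telehealth-acquired). Shipped so the
#' metric arithmetic can be exercised at desk scale without downloading the
#' underlying databases.
#'
#' `error_rate_consistent` records whether the printed error-rate percentage
#' is reproduced by `100 * (FP + FN) / TB` from the same row's counts; the
#' telehealth rows are not internally consistent in the source table and are
#' flagged `FALSE`.
#'
#' @return A tibble with columns `dataset`, `description`, `algorithm`,
#'   `tp`, `fp`, `fn`, `tb`, `failed_detection`, `error_rate_pct`,
#'   `error_rate_consistent`.
#' @examples
#' counts <- reference_counts()
#' with(counts[1, ], total_error_rate(beat_counts(tp, fp, fn, tb)))
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_counts.csv", package = "qrsdetect",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
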