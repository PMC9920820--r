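Package: qrsdetect
Title: Real-Time QRS Detection with a Simplified Pan-Tompkins Algorithm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects QRS complexes (R peaks) in single-lead electrocardiogram
    recordings using a streamlined variant of the Pan-Tompkins algorithm that
    analyses only the moving-window-integrated signal with a single averaged
    RR interval for search-back, alongside a faithful implementation of the
    original dual-signal Pan-Tompkins detector for comparison. Includes the
    classical band-pass/derivative/squaring/integration conditioning chain,
    beat-by-beat evaluation against reference annotations with the 150 ms
    ANSI/AAMI matching window (total error rate, sensitivity, positive
    predictive value, accuracy, F1), a deterministic seedable synthetic ECG
    generator covering sinus, irregular, paced and tall-T morphologies, and
    readers/writers for WFDB records and CSV time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
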