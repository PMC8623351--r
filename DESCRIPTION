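Package: tscscalib
Title: Automated Calibration of Transcutaneous Spinal Cord Stimulation from
    Evoked EMG Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for calibrating transcutaneous spinal cord stimulation
    (tSCS) from multi-muscle evoked electromyography (EMG) recorded during a
    paired-pulse, multi-electrode, amplitude-ramp protocol. The pipeline
    detects stimulation artifacts by double differentiation of the raw EMG,
    time-aligns and zero-phase filters the sweeps, gates repetitions by
    root-mean-square-error similarity, averages them, extracts peak-to-peak
    response amplitudes and the paired-pulse suppression ratio, classifies
    each response as posterior root-muscle reflex, presumed M-wave, no
    response, or invalid, and recommends an electrode position and a
    sub-threshold therapy amplitude via a lexicographic ranking and a
    normalized cost function. A seeded simulator generates synthetic
    calibration sessions with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
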