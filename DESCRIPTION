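Package: ppgtrace
Title: Heart Rate Estimation from Smartphone Video Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating average heart rate from fingertip-video
    photoplethysmography (PPG). Extracts a per-frame red-channel brightness
    trace from video frames or CSV files, band-pass filters it with a
    Butterworth filter, sharpens heartbeats by double differentiation,
    detects pulse peaks, and estimates the average pulse-to-pulse interval
    with a harmonic-tolerant grid-search loss that absorbs missed and
    double-counted beats. Includes study-level baseline-normalised
    log heart-rate change ratios with configurable quality control, and a
    synthetic PPG generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
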