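Package: wearbench
Title: Benchmarking Wearable Physiological Sensors Against Laboratory References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark pipeline for simultaneously recorded physiological
    time series from a calibrated laboratory recorder and consumer wearables.
    Reads per-device sensor streams (heart rate, inter-beat interval, ECG,
    skin conductance), aligns them on a common millisecond grid, derives
    inter-beat intervals and complex-demodulation heart-rate-variability
    band amplitudes from ECG, and quantifies pairwise agreement with a
    correlation battery (coefficient of determination, lagged
    cross-correlation with stationarity handling, maximal information
    coefficient, and an MIC minus R-squared nonlinearity classification)
    and a similarity battery (dynamic time warping and global plus
    moving-window discrete Frechet distances on rescaled signals). Results
    are aggregated into sorted participant-by-pair benchmark matrices. A
    seeded synthetic-cohort generator emulating a stepped ergometer protocol
    provides fully reproducible inputs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    ggplot2,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
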