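Package: nirscomp
Title: Compensatory-Movement Detection from Muscle NIRS Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting compensatory trunk movements during upper-limb
    rehabilitation from multichannel muscle near-infrared spectroscopy (NIRS)
    recordings. Implements the full analysis chain: preprocessing of
    deoxy-/oxyhemoglobin time series (missing-sample padding, zero-phase
    Butterworth low-pass filtering, empirical-mode-decomposition baseline
    removal), correlation-based (CBSI) and differential-based (DBSI) signal
    improvement, linear-fitting-slope activation-segment detection,
    sliding-window time-domain feature extraction, and four-class support
    vector machine evaluation with stratified cross-validation. A synthetic
    trunk-muscle NIRS generator with per-stage ground truth drives simulation
    studies and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
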