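Package: pulsedepth
Title: Depth Classification of Radial-Artery Pulses from Multi-Pressure
    Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the depth quality (floating, middle-depth,
    sunken) of radial-artery pulses recorded under stepped hold-down
    pressures.  Raw single-channel pulse waveforms are segmented by
    pressure step, baseline-corrected by polynomial detrending,
    ensemble-averaged per beat, and reduced to per-step pulse strengths.
    Depth coefficients are computed either from the interpolated
    pressure-strength curve or from shallow/deep strength ratios, and
    turned into class labels by single- or dual-threshold decision rules
    with a reject (middle-depth) option.  Threshold sweeps, selection-rate
    frontiers, inter-rater agreement statistics (accuracy, Matthews
    correlation coefficient) and group comparisons (Welch t-tests) support
    validation against human raters, and a synthetic pulse-cohort
    generator with known ground truth makes the full pipeline testable
    without a pulse-taking device.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
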