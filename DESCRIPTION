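Package: insolegait
Title: Gait Analysis Pipeline for a 64-Cell Optoelectronic Pressure-Sensitive Insole
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete data-processing and gait-analysis pipeline for a 64-cell
    optoelectronic pressure-sensitive foot insole: two-exponential voltage-to-force
    calibration (evaluation, numeric inversion, per-cell and aggregate nonlinear
    least-squares fitting), signal conditioning (de-offset, 40 Hz low-pass,
    1200 to 100 Hz decimation), vertical ground reaction force and centre-of-pressure
    computation with a -20 N stance threshold, threshold-based gait-phase
    segmentation (Stance 1 / Stance 2 / Swing), temporal gait parameters
    (stance, swing, double support, cadence), step-profile resampling and
    comparison statistics (NRMSE, Pearson correlation, MAE of stance duration),
    and a synthetic gait simulator that emulates the transduction law so every
    pipeline stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
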