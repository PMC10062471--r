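Package: insoleGRF
Title: Ground Reaction Force Estimation and Validation for Two-Sensor
    Pressure-Sensing Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to calibrate and validate low-cost insole pressure
    sensors (IPS) against a laboratory force plate (FP) for estimating
    resultant ground reaction force (GRF) during walking.  The package
    covers the full measurement pipeline: a synthetic gait generator with
    known ground truth (double-peaked stance waveforms, a monotone
    force-resistance sensor law with drift and noise, step calibration
    trials, stomp synchronization events), signal conditioning
    (band-limited resampling, binomial smoothing, Butterworth low-pass
    filtering, baseline zeroing), heel-strike detection and gait-cycle
    segmentation, per-sensor quadratic calibration of conductance to
    force, a two-coefficient total-force calibration accounting for the
    unsensed midfoot, Bland-Altman agreement analysis with stratified
    two-fold cross-validation, and a Monte-Carlo simulation (with a
    closed-form bivariate-normal oracle) of overload detection during
    partial weight bearing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
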