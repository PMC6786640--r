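Package: proteoclock
Title: Elastic-Net Proteomic Age Clocks for Presymptomatic Tumor Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits elastic-net "proteomic clocks" (age regressions on
    mass-spectrometric peak intensities) separately to control and
    tumor-destined cohorts, scores each sample by its deviation from the two
    clocks (the delta-Pr criterion derived from Bayesian posterior
    differencing), evaluates the resulting two-dimensional presymptomatic
    classifier by per-timepoint ROC/AUC, estimates a global permutation-based
    false discovery rate for the clock difference, and characterizes the
    entropy kinetics of the clock residuals across sampling ages. Ships a
    synthetic two-group cohort generator that emulates the cross-sectional
    design of a CSF proteomic rat study so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
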