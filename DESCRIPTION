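Package: budforc
Title: Process-Based Spring Phenology Models with Temperature and
    Photoperiod Triggers of Bud Growth Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and calibrates process-based models of spring
    phenology (first leaf unfolding, first flowering) for deciduous trees.
    The central model family initiates bud growth when either daily mean
    air temperature or daylength first exceeds a fitted threshold, then
    accumulates a sigmoid forcing response of temperature until a critical
    state is reached. Includes three classical one-phase comparison models
    (UniForc, Photothermal, M1), Metropolis simulated-annealing
    calibration against RMSE, evaluation by NSE, AICc, Pearson
    correlation and leave-one-out cross-validation, Forsythe daylength
    computation, derived winter/spring climate metrics, a synthetic
    station-network weather and phenology generator, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
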