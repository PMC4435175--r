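Package: amevaHAR
Title: Discrete Physical Activity Recognition with Ameva Discretization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Physical activity recognition from triaxial accelerometer
    streams using discrete variables. Per-window statistics are
    discretized with the chi-squared based Ameva criterion, and windows
    are classified by majority voting over an activity-interval
    likelihood matrix. Includes cadence (activity cycles per minute)
    estimation from the spectral peak, adaptive controllers for dynamic
    sampling rate and duty cycling of the sensor, a synthetic signal and
    feature-table generator for end-to-end testing, and a command-line
    interface covering the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
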