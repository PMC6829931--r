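Package: seatcomp
Title: Detecting Compensatory Trunk Movements from Seat Pressure Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and categorizes compensatory trunk movements (trunk
    lean-forward, trunk rotation, shoulder elevation) during seated reaching
    from body-pressure-mat recordings. Provides readers and writers for an
    ASCII pressure-frame dialect, per-sensor bias-offset correction,
    center-of-pressure and pressure-ratio feature extraction, k-nearest
    neighbour and linear support-vector-machine classification under
    subject-grouped cross-validation, confusion-matrix metrics, a surface-EMG
    root-mean-square preprocessing chain, and a seeded synthetic generator of
    labeled seated-pressure and sEMG trials for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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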