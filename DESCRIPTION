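Package: insolefall
Title: Insole-Sensor Fall Detection from Low- and High-Acceleration Activities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for classifying falls against eight low- and
    high-acceleration activities of daily life from a shoe-insole sensor
    system (a tri-axial accelerometer plus four force-sensitive resistors
    sampled at 20 Hz). Implements filtered Sum-Vector-Magnitude windowing,
    a 45-feature registry combining accelerometer moments, spectral energy,
    filtered-magnitude extrema and force-sensor gait features, a
    polynomial-kernel multiclass support vector machine evaluated by
    leave-one-subject-out cross-validation, and genetic-algorithm wrapper
    feature selection that minimises fall false positives plus false
    negatives. A synthetic protocol simulator generates labelled trials
    emulating the 20-subject study design so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
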