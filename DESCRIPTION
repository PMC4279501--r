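Package: skigears
Title: Classification of Cross-Country Ski Skating Gears from Chest
    Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies the sub-techniques ("gears" G2 left/right, G3, G4
    left/right) used during cross-country ski skating from a triaxial
    chest-worn accelerometer. Streams are smoothed with time-domain
    Gaussian kernels that are exact under irregular sampling, segmented
    into movement cycles at low-frequency vertical-acceleration minima,
    time-normalized to fixed-length trajectories in acceleration space,
    and classified by per-gear first-order Markov chains of multivariate
    Gaussian distributions.  Includes an evaluation layer (confusion
    matrix, per-gear accuracy, start-up/transition error breakdown,
    paired t-test and Pearson correlation), a calibrated synthetic-session
    generator for end-to-end validation, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
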