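Package: hlmstab
Title: Bioanalytical Method Validation and Microsomal Metabolic Stability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative bioanalytical workflow around
    LC-MS/MS assays run in human liver microsomes: weighted linear
    calibration with back-calculation and LOD/LOQ estimation, FDA-style
    validation statistics (precision, accuracy, matrix effect, extraction
    recovery, storage stability), substrate-depletion kinetics (log-linear
    regression, in vitro half-life and well-stirred-model intrinsic
    clearance), and weighted aggregation of 12-criterion green-analytical-
    chemistry scores. Includes synthetic-data generators that emulate the
    statistical structure of instrument data so every stage is testable
    offline, plus CSV readers and deterministic JSON/markdown/TSV reports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
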