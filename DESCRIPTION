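Package: usvscore
Title: Detection, Parameterization and Classification of Rodent Ultrasonic Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Environment-agnostic detection of rat ultrasonic vocalizations (USVs)
    in spectrograms of high-sample-rate WAV recordings, ridge-based acoustic
    parameterization, logistic detection-confidence scoring, random-forest
    classification into a five-call composite scheme (fixed-frequency 50-kHz,
    frequency-modulated 50-kHz, trilled 50-kHz, long and short 22-kHz calls),
    and the full evaluation toolkit: detection sensitivity/precision against
    hand-scored ground truth, per-class precision/recall/F1/support, Cohen's
    kappa, and two-proportion tests. Includes a seeded synthetic-USV generator
    so every stage is testable without laboratory recordings, a headless
    hand-scorer training-session engine with immediate feedback, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    matrixStats,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
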