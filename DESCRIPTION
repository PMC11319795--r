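Package: echosway
Title: Muscle Ultrasound Texture, Posturography, and Their Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies skeletal-muscle composition from B-mode ultrasound
    images (echo-intensity, muscle and subcutaneous-fat thickness, and
    gray-level co-occurrence matrix texture features) and postural stability
    from force-plate recordings (band-pass filtered centre-of-pressure sway),
    and links the two with group-comparison statistics, empirical ROC
    classification of young versus older muscle with paired AUC tests, and a
    ridge-regularized canonical correlation analysis with leave-one-out
    regularization selection and permutation inference. Ships a synthetic-data
    generator (cohorts, speckle images, force-plate signals) with known ground
    truth so the full pipeline runs and is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    png,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
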