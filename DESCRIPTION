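Package: eegmark
Title: Interpretable Five-Feature Epileptic EEG Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of epileptic states from single-channel EEG using five
    interpretable features: spike-wave and sharp-wave energy extracted by
    duration-amplitude criteria, Higuchi fractal dimension, permutation
    entropy, and a dynamic feature increment summarising state-transition
    dynamics. Includes readers for plain-text and MAT v5 single-channel EEG
    segments, overlapping-window segmentation, a leakage-safe
    recording-stratified cross-validation harness over five classical
    classifiers, exact Shapley-value attribution for the five-feature models,
    and a seeded synthetic EEG generator with ground-truth event logs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    rpart,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
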