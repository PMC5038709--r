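Package: psychstate
Title: Emergency Psychiatric State Prediction from Wearable Biosensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the psychiatric state of a monitored subject as a
    three-state hidden Markov chain (Normal, Atypical, Emergency) observed
    through wearable biosensor signals (ECG, EDA, BVP, surface EMG),
    psychiatric rating-scale scores and patient-history flags.  Provides a
    state-conditioned synthetic cohort generator, per-sensor signal feature
    extraction, an mRMR / PCA / kernel discriminant feature pipeline, hidden
    Markov model training by Viterbi path counting and by stochastic
    variational inference, Viterbi decoding, a longest-run / highest-frequency
    / most-recent-state ensemble with majority voting for window-level
    prediction, and diagnostic evaluation (sensitivity, specificity,
    F-measure, accuracy, one-vs-rest AUC, diagnostic odds ratio) with
    subject-stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
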