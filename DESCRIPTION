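Package: bcgaf
Title: Atrial Fibrillation Detection from Multi-Site Ballistocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects atrial fibrillation from bed-sensor ballistocardiogram
    (BCG) recordings acquired simultaneously at several body locations.
    Implements sliding-block segmentation, per-block standardization,
    amplitude-based motion-artifact rejection, Hanning-windowed FFT spectral
    featurization, classifier tuning with participant-grouped stratified
    cross-validation, cross-location robustness evaluation, and decision-level
    OR-rule fusion of per-sensor predictions.  Ships a seeded synthetic
    multi-sensor BCG cohort generator that reproduces the harmonic-comb
    spectral structure of sinus rhythm and its disappearance in atrial
    fibrillation, so the whole pipeline can be exercised and tested without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rpart,
    randomForest,
    glmnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
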