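Package: ecgimage
Title: ECG Signal-to-Image Transformation and Ventricular Arrhythmia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms raw ECG time series into 32x32 binary images by
    segmentation and inverse vectorization, extracts fixed-length deep-style
    features from pluggable backends, fuses feature blocks by concatenation,
    selects features by histogram entropy, and evaluates SVM, discriminant and
    KNN classifiers for rhythm classification (normal sinus rhythm,
    ventricular tachycardia, ventricular fibrillation, ventricular flutter).
    Includes a seeded synthetic ECG generator with class-distinct rhythm
    morphology, a minimal WFDB-dialect reader/writer, and stratified
    holdout / k-fold evaluation reporting sensitivity, specificity, FNR,
    accuracy and F-score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    MASS,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
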