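Package: bedbeat
Title: Ballistocardiographic Heartbeat Detection from Bed-Mounted Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for unobtrusive heartbeat
    detection on a smart bed. Generates bed-frame 3-axis accelerometer traces
    with a co-registered finger-pulse (photoplethysmographic) channel, applies
    a 0.5-20 Hz Butterworth bandpass and first-difference rectification,
    segments signals into 125-sample windows, extracts a 12-feature vector per
    window, derives per-window binary heartbeat labels from pulse peaks, and
    compares eight classifiers (logistic regression, linear discriminant
    analysis, k-nearest neighbours, a classification tree, Gaussian naive
    Bayes, a radial-kernel support vector machine, a 100-tree random forest
    and a small multilayer perceptron) under stratified 10-fold
    cross-validation and leave-one-subject-out evaluation, with per-class
    precision, recall, F1, macro and support-weighted averages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    rpart,
    e1071,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
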