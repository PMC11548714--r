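Package: pfmqa
Title: Quality Assessment of Pelvic Floor Muscle Contractions from Dynamometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing pelvic floor muscle (PFM) contraction quality from
    intra-vaginal dynamometric force recordings. Provides a one-dimensional
    convolutional neural network that separates PFM contractions from
    non-contractions (rest, cough, push), a rule-based piecewise-linear trapezoid
    model that locates contraction corner points and extracts clinical features
    (rising/falling slope, area under the contraction, peak and average force,
    contraction time, muscle relaxation), an overall contraction rating, and
    classifiers that predict the Modified Oxford Scale strength grade with a
    +/-1-class tolerance. Includes Butterworth-filtered decimation of legacy
    1024 Hz recordings with reconstruction-fidelity metrics, shared error metrics
    (MAE, RMSPE), a seeded synthetic dynamometry generator with analytic ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    nnet,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
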