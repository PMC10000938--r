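Package: crydx
Title: Cepstral Feature Fusion and Classification for Newborn Cry Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying newborn cry episodes as
    healthy or pathologic from audio. Provides a seeded source-filter synthetic
    cry generator, WAV and segment-label ingestion, short-time framing, mel and
    gammatone (ERB) cepstral feature extraction with delta and delta-delta
    stacking, canonical correlation analysis (CCA) feature-level fusion,
    Gaussian-kernel SVM and LSTM classifiers, grid/random/Bayesian
    hyperparameter optimization, and a binary diagnostic evaluation suite
    (accuracy, recall, specificity, precision, NPV, F-score, Matthews
    correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    lhs,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
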