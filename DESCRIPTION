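Package: eegmvpa
Title: Time-Resolved EEG Decoding, Representational Similarity Analysis and
    Bayes-Factor Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for time-resolved multivariate pattern analysis
    of epoched EEG: pairwise and class-level linear discriminant decoding with
    shrinkage-regularised covariance and leave-one-block-out cross-validation,
    representational similarity analysis against behavioural rating structure
    with a leave-one-participant-out noise ceiling, Jeffreys-Zellner-Siow
    interval-null Bayes-factor time-series inference with onset and peak
    latency estimation, and low-level image-statistics controls. Includes a
    synthetic-data generator that emulates rating tables, stimulus images and
    rapid serial visual presentation epoch structure with known ground truth,
    so every analysis stage can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
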