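Package: aptascreen
Title: Electrochemical Aptasensor Signal Analysis and Diagnostic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired before/after electrochemical measurements
    from aptamer-based biosensors. Simulates cyclic voltammograms and impedance
    spectra for lung-cancer (LC) versus healthy (H) plasma cohorts, extracts
    voltammetric peak features (potential, height, onset, width, shape, area) and
    Cole-Cole complex-capacitance features, fits equivalent circuits with constant
    phase elements and generalized Warburg diffusion by complex nonlinear least
    squares, computes delta and increment change-features, and screens single,
    coupled and tripled feature combinations with a leave-one-out cross-validated
    bank of k-nearest-neighbour, linear support-vector and logistic classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
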