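Package: connage
Title: Sensorimotor Functional Connectivity and Connectome-Based Age Prediction
Version: 0.1.0
Authors@R: person("J.", "Carter", email = "jcarter@example.org", role = c("aut", "cre"))
Description: Tools for studying age effects on resting-state functional
    connectivity of the sensorimotor system and for predicting chronological
    age from connectivity features. Includes a synthetic cohort generator with
    known ground truth, framewise-displacement motion quality control,
    band-pass filtering and nuisance regression, seed-based connectivity maps
    with Fisher r-to-z transform, covariate-adjusted group statistics with
    Benjamini-Hochberg FDR and cluster-extent filtering, univariate and
    multivariate (nested leave-one-out cross-validated linear epsilon-SVR)
    age-prediction frameworks with permutation inference, and linear SVM
    group classification with ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
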