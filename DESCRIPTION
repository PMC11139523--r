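Package: sigxae
Title: Mutational Signature Extraction with an Explainable Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo extraction of single-base-substitution (SBS-96) mutational
    signatures from cancer mutation catalogues with a hybrid autoencoder: a
    nonlinear encoder and a linear non-negative decoder trained under a Poisson
    likelihood with minimum-volume (log-determinant) regularization of the
    signature matrix. Model selection follows the NMFk idea: multinomial
    bootstrap augmentation of the catalogue, repeated training from random
    initializations, consensus clustering of decoder weights by linear-assignment
    matching on cosine distance, silhouette-based stability filtering, and
    selection of the stable solution with the lowest reconstruction error.
    Also provides sparse exposure refitting against a fixed signature set
    (frozen decoder with L1 penalties), a parametric simulator of synthetic
    tumour cohorts with known ground truth, and evaluation utilities
    (Hungarian matching of signatures, precision/sensitivity/F1 recovery
    curves, and exposure-based tumour-type classification).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
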