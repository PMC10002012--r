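Package: histovae
Title: Reconstruct-Then-Classify Analysis of Breast Histopathology Patches
    with Variational Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reconstruct-then-classify pipeline for invasive
    ductal carcinoma (IDC) breast-histopathology image patches. Patches are
    reconstructed by a convolutional variational autoencoder (VAE), or by a
    denoising variant that corrupts encoder inputs with Gaussian noise while
    scoring reconstructions against the clean images, and the reconstructions
    are classified by a small strided convolutional neural network. The
    package ships its own seeded, deterministic training engine (im2col
    convolutions via RcppArmadillo, Adam, reparameterised latent sampling,
    evidence-lower-bound loss), a full binary-classification metric battery
    (support-weighted precision/recall/F1/specificity, Cohen's kappa,
    tie-corrected ROC AUC), preprocessing of labelled PNG patch directories,
    and a seeded two-class synthetic texture generator so the whole pipeline
    is testable without the external patch dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
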