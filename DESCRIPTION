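Package: riemcell
Title: Unsupervised Microscopy Analysis on the SPD Manifold and in Latent Morphology Space
Version: 0.1.0
Authors@R:
    person("riemcell", "developers", email = "riemcell@example.org", role = c("aut", "cre"))
Description: Tools for unsupervised analysis of grayscale microscopy images of
    cultured cells.  One arm represents local image texture by region covariance
    descriptors, i.e. symmetric positive definite (SPD) matrices, learns a
    dictionary of tangent-space atoms with an amortized linear encoder under a
    Stein-divergence reconstruction loss, and renders per-class probability maps
    for unsupervised segmentation.  The other arm embeds masked single-cell
    crops with a convolutional autoencoder (optionally with a shape-conditioned
    cross-attention bottleneck), projects the L2-normalized latent vectors to
    two dimensions with Barnes-Hut t-SNE under a cosine metric, clusters the
    embedding with HDBSCAN, and summarizes per-cluster morphology.  A synthetic
    scene and cell-crop generator makes the whole pipeline testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    png,
    Rtsne,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
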