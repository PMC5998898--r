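Package: ramamix
Title: Real-Valued Protein Backbone Dihedral Angle Prediction via
    Ramachandran Basin Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hybrid clustering-plus-classification workflow for predicting
    real-valued protein backbone dihedral angles (phi, psi) with per-residue
    confidence bounds. Dihedral angle pairs are embedded as
    (cos phi, sin phi, cos psi, sin psi) vectors and clustered by k-means
    into Ramachandran basins; a per-residue classifier predicts basin
    membership probabilities from sequence-profile features; real-valued
    angles are reconstructed as probability-weighted mixtures of the
    normalized cluster centers, and per-residue standard deviations follow
    from probability-weighted in-cluster circular variances. Includes
    bivariate von Mises (cosine model) densities with Bessel-series
    normalization for mixture log-likelihood model selection, entropy-loss
    cluster-number selection, periodicity-aware evaluation metrics, a
    synthetic Ramachandran protein generator, and TSV/JSON/PSSM readers and
    writers with a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
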