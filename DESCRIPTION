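Package: elastinv
Title: Full-Field Elastic Modulus Recovery in Hyperelastic Soft Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Physics-informed neural networks and an adjoint inverse finite
    element baseline for recovering heterogeneous elastic modulus maps of
    soft-tissue-like 2D hyperelastic materials from full-field Green-Lagrange
    strain data. Includes a synthetic data generator (crossed triangulations of
    the unit square, Gaussian random field and image-derived stiffness
    patterns, a P1 finite element forward solver under equibiaxial stretch),
    three constitutive models (compressible Neo-Hookean in plane strain or
    plane stress, Mooney-Rivlin, Gent), twenty network architecture variants
    with Fourier features and hard displacement boundary constraints, strain
    noise injection, recovery-quality metrics, and the delentropy image
    complexity measure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    png,
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
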