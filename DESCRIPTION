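Package: gelimpute
Title: Imputation and Differential Analysis for Two-Dimensional Gel Spot Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the statistical analysis of two-dimensional gel
    electrophoresis (2-DE) spot-volume matrices with missing values.
    Implements a three-step pipeline: imputation of missing spot volumes
    (row average, k-nearest neighbours, the least-squares/EM regression
    family with spot-wise, array-wise, combined and adaptive correlation
    structures, and NIPALS principal-component reconstruction), per-spot
    two-group testing (Welch t, exact/Monte-Carlo permutation t,
    Chebyshev-bound test, and normal, percentile and pivotal bootstrap-t
    constructions), and multiple-testing error control (per-comparison,
    Benjamini-Hochberg, and generalized family-wise error rate by
    augmentation).  Also provides a synthetic spot-matrix generator with
    intensity-dependent missingness and Monte-Carlo benchmarking of
    imputation accuracy (normalized RMSE, average spot variance) and of
    discovery agreement across tests and imputation methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
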