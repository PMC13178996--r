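Package: rnaprecis
Title: Rotameric RNA Backbone Suite Conformers from Low-Detail Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts full-detail rotameric RNA backbone suite conformers from a
    sparse five-atom-per-suite representation (the phosphorus plus the two
    glycosidic bonds). Sugar puckers are gated with the Pperp criterion,
    low-detail suites are expressed in multicentred constrained size-and-shape
    (MUCCSS) coordinates on a product manifold, per-cluster Frechet means and
    tangent-space covariances summarise training clusters, and a regularized
    Bayesian Mahalanobis classifier ranks candidate conformer clusters. The
    training side clusters seven-dihedral suite data on the torus with an
    average-linkage tree, adaptive iterative cutting and small-sample circular
    mode hunting. A synthetic suite generator builds Cartesian suites from
    internal coordinates so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
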