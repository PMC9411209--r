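Package: manifoldcost
Title: Topology Cost Function for Low-Dimensional Data Manifolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of low-dimensional manifold topologies for
    reduced-order modeling and embedding quality control. Computes the
    kernel-weighted normalized variance of user-selected dependent variables
    across a sweep of length scales, its derivative in log10 scale space, and a
    penalized-integral cost that rewards large feature sizes and penalizes
    non-uniqueness (overlapping manifold states). Includes a suite of data
    scaling methods, a principal-component outlier classifier, PCA projection
    utilities, cost-guided backward feature selection, and synthetic toy
    generators (Gaussian bumps, sine superpositions, overlap functions, class
    clouds, swiss roll) for validating the metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
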