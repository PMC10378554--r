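Package: copulamodules
Title: Low-Dimensional Modules of Count Dependence via Vine Copulas and
    Weighted NMF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects the dependence structure of multivariate count data
    (e.g., neural spike counts) with a C-vine pair-copula construction.
    Discrete margins are handled with the distributional transform; bivariate
    copula densities are estimated non-parametrically with a rational-quadratic
    spline normalizing flow (uniform base) or a fast smoothed-histogram
    estimator; pairs are screened with a two-sample two-dimensional
    Kolmogorov-Smirnov independence test. The resulting collection of copula
    densities is summarized by a tail-weighted non-negative matrix
    factorization ("copula modules"), with speckled cross-validation for rank
    and regularization selection. Includes generators for parametric
    (Clayton/Frank) benchmark copulas and synthetic count populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
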