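Package: aleoverlap
Title: Coordinate-Based Meta-Analysis with Activation Likelihood
    Estimation and Network Overlap Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coordinate-based meta-analysis of neuroimaging foci
    using the revised activation likelihood estimation (ALE) algorithm:
    sample-size-dependent Gaussian modelled-activation maps, analytic null
    distributions by non-linear histogram integration, cluster-level
    family-wise-error thresholding by Monte Carlo relocation of foci,
    minimum-statistic conjunction of thresholded networks, volume-matched
    network comparison, and per-region overlap tables against user-supplied
    atlas masks.  Includes a synthetic foci generator with planted
    convergence loci so every pipeline stage can be exercised and calibrated
    at desk scale, plus tidy accessors and ggplot2 visualisations of
    networks, null distributions and overlap tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
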