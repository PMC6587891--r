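Package: hybridFBN
Title: Hybrid First- and Second-Order Functional Brain Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and analysis of hybrid functional brain
    connectivity networks from regional fMRI time series. Builds
    triplet-based second-order networks that capture ordinal
    nearest-neighbour structure among brain regions, fuses them with
    first-order Pearson correlation networks, and provides the full
    downstream pipeline: non-negative elastic-net edge selection, Gaussian
    kernel discriminant projection, nearest-neighbour classification under
    repeated stratified cross-validation, DeLong AUC comparison,
    graph-topological summaries, and between-group connectivity-alteration
    (SAC) biomarker ranking. Includes a synthetic two-group cohort
    generator with planted covariance differences for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
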