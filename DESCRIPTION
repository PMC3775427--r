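Package: netshift
Title: Compare Task Coactivation and Resting-State Brain Network Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a meta-analytic coactivation connectivity matrix and a
    resting-state correlation matrix over a shared set of spherical regions of
    interest, binarizes both at matched sparsity, and compares their graph
    configurations (global efficiency, mean clustering coefficient, Newman's
    modularity, degree and hub structure). Statistical comparison uses an
    edge-exchange permutation null that mixes the non-shared edges of the two
    networks, and hub shifts are assessed with a sorted degree-difference
    envelope. Includes a synthetic-data module that generates seed-by-target
    coactivation count matrices and multi-subject ROI time series with planted
    modular covariance, hubs, motion traces and nuisance regressors, so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    RNifti,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
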