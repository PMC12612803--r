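Package: porespeed
Type: Package
Title: Microstructure-Dependent Speed of Sound in Digital Skull-Bone Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates digital skull-mimicking bone phantoms made of spherical
    red-marrow pores randomly placed in a cortical background, propagates
    pulsed and continuous plane waves through them with a first-order k-space
    pseudospectral solver for heterogeneous lossy fluid media, and measures
    group velocity, phase velocity and steady-state phase over a
    through-transmission measurement plane by the substitution method.
    Includes an independent transfer-matrix model for layered lossy media used
    as an analytic cross-check, CFL and duration convergence tests, parameter
    sweep orchestration with caching, and ggplot2-based reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    utils,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
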