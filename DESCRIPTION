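Package: subvolreg
Title: Subvolume-Based Rigid Registration Precision for Repeat Prostate MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the size of the registration volume affects
    the precision of rigid registration of repeat pelvic magnetic resonance
    series. Implements a mean-square intensity metric restricted to a binary
    registration volume (the delineated prostate gland and isotropic
    millimetre margin expansions of it, versus the full image grid), a
    versor-parametrised regular-step gradient-descent optimiser, a synthetic
    pelvic phantom generator with known rigid prostate motion for validation,
    and a precision analysis based on centre-of-mass distances between
    prostate delineations: per-axis standard deviations, variance F-tests,
    norm-improvement tables and best-volume frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
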