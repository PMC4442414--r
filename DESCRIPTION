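Package: balloonid
Title: Identifiability and Sensitivity Analysis of the fMRI Balloon Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the four-state Balloon hemodynamic model of the fMRI
    BOLD response under configurable block, event-related and mixed stimulus
    paradigms, and quantifies parameter identifiability three ways:
    one- and two-parameter relative-error grid scans of the BOLD signal,
    local sensitivity via Jacobian pseudoinverse projections, and
    variance-based (Sobol-type) first- and second-order sensitivity indices
    estimated by Monte Carlo. Results are returned as tibbles with broom-style
    tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr
Config/testthat/edition: 3
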