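Package: tcellvax
Title: Impulsive ODE Modeling of CD8+ T Cell Responses to Adenovirus
    Vaccination and Tumor Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-compartment (lymph node, blood, tumor)
    impulsive ordinary differential equation model of the cytotoxic CD8+
    T cell response elicited by replication-deficient adenovirus
    vaccination against a tumor antigen, and the resulting suppression of
    B16F10 melanoma growth. Provides a fixed-step fourth-order
    Runge-Kutta integrator with exact vaccination impulses, closed-form
    tumor-free and high-tumor equilibria with linearized stability
    analysis (analytic Jacobian, closed-form spectra, Routh-Hurwitz
    criterion), genetic-algorithm parameter calibration against
    time-series observations using a normalized error-plus-slope fitness,
    a synthetic data generator emulating the calibration study design,
    and in-silico vaccination-schedule experiments with tidy summaries
    and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
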