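Package: chargemig
Title: Pump-Probe Kinetics and Model Many-Body Dynamics of Charge
    Migration in Ionised Adenine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis chain for attosecond-pump / near-infrared-probe
    studies of correlation-driven charge migration in ionised nucleobases.
    Generates synthetic delay-resolved ion time-of-flight datasets and
    intensity series, extracts and averages ion traces, fits rate-equation
    curve models (instrument-response-convolved step-decay and rise-decay)
    with bootstrap confidence intervals, estimates shake-up rates and
    characteristic times from Fermi's golden rule on few-orbital model
    molecules, propagates one-body density matrices at the mean-field and
    GKBA second-Born levels (with an exact-CI oracle), and integrates
    out-of-plane electron density from Gaussian-cube orbitals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
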