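Package: barrierkin
Title: Permeability Kinetics for Microfluidic Blood-Brain and Blood-Tumor
    Barrier Chips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for tracer-permeability assays on
    two-compartment microfluidic barrier chips (an outer perfused channel
    and a central compartment separated by a porous interface). Provides a
    mechanistic two-compartment transport simulator with flow and
    efflux-transporter clearance, a fluorescence time-lapse renderer with
    shot and read noise, ROI sum-intensity quantification of multi-page
    TIFF stacks, estimation of the unidirectional uptake transfer constant
    k_in from the (C_CC + C_PF)/C_PF ratio-versus-time regression with
    linear-uptake-zone selection, and group-comparison statistics
    (mean +/- SEM, one-way ANOVA with Tukey HSD, Welch t tests, F tests of
    variances, fold changes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
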