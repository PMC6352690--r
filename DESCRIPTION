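Package: vwskin
Title: Veronda-Westmann Characterization of Skin-Surrogate Uniaxial Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for hyperelastic characterization of elastomeric
    human-skin surrogates from uniaxial tension tests. Converts raw universal
    testing machine load-extension records into standardized true
    stress-stretch curves through a seven-step post-processing protocol
    (slack trimming, yield truncation, origin shifting, engineering-to-true
    conversion, polynomial trend fitting, grid standardization, stretch
    conversion), fits the two-parameter Veronda-Westmann strain-energy model
    by bounded nonlinear least squares, and extracts linear-regime tissue
    metrics (low- and high-stretch elastic moduli, ultimate tensile stress).
    Ships a catalog of surrogate elastomer compositions with per-body-site
    model coefficients, and a synthetic raw-record generator so the whole
    pipeline is testable without experimental data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
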