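Package: salinelc
Title: Dose-Response Modelling and Salinity Comparison for Fish Acute-Toxicity Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits two-parameter log-logistic survival curves to replicate-level
    acute-toxicity bioassay data by binomial maximum likelihood, estimates
    lethal concentrations (LC10, LC50) with delta-method standard errors and
    Nagelkerke pseudo-R-squared goodness of fit, and tests whether LC values
    differ between two salinity treatments with a Monte Carlo stratified
    label-permutation test backed by an exhaustive-enumeration oracle. Includes
    a synthetic-bioassay generator emulating a standard estuarine-fish
    range-finding design (six concentrations with a solvent control, six
    replicates of two organisms, two salinities) for parameter-recovery,
    type-I-error and power experiments, plus measured-versus-nominal chemistry
    QC summaries and a scriptable end-to-end pipeline.
License: MIT
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
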