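Package: fermadequacy
Title: Fermentation Scenarios for Folate and Cobalamin Intake Adequacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how fermentation-driven changes in the folate and
    cobalamin content of injera (Ethiopian fermented teff flatbread) alter
    estimated nutrient adequacy in women of reproductive age. Provides a
    synthetic 24-h dietary recall generator with known ground truth, a
    composition-table scenario engine, a Multiple Source Method style
    usual-intake estimator (covariate regression, two-parameter Box-Cox
    transformation, between/within-person variance decomposition, shrinkage,
    bias-corrected back-transformation), and the EAR cut-point and
    probability-of-adequacy statistics, assembled into a reproducible
    reporting pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
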