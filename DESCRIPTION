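Package: oakextract
Title: Factorial-Design and Neural-Network Modelling of Wood-Chip
    Antioxidant Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing solvent extraction of antioxidant
    metabolites from wood chips with a three-level full factorial design.
    Builds coded-factor designs, fits the linear-with-interactions response
    model by ordinary least squares with PRESS/predicted R-squared and
    adequate-precision diagnostics, performs Derringer-Suich desirability
    optimization over the factor cube, trains a small multilayer perceptron
    by Levenberg-Marquardt with validation-based early stopping, and
    compares factorial and neural predictions by MAE, RMSE and R-squared.
    Ships the 27-run Turkey oak (Quercus cerris) extraction dataset the
    methods were developed on, plus a synthetic response-surface generator
    for validation studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
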