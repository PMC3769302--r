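Package: carbonrisk
Title: Global Change Risk Assessment for Forest Carbon Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for assessing global change risks to forest
    carbon stocks. Starting from plot-level carbon densities overlaid on
    current and projected Koeppen-Geiger climate zones, the package computes
    an across-zone coefficient of variation of median carbon densities (the
    likelihood of stock change), projects national stock totals to a target
    year by per-pool linear regression, projects future variability via
    zone-shift median imputation, and places the five UNFCCC forest carbon
    pools in a consequence-by-likelihood risk matrix with societal response
    categories. Includes a synthetic national-inventory plot simulator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
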