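Package: ncsaccount
Title: Natural Climate Solutions Portfolio Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accounting framework for a portfolio of natural climate solutions
    (NCS): 21 pathway-specific estimators of annual climate mitigation on
    forest, agricultural, grassland and wetland lands, CO2-equivalent
    conversion of CH4 and N2O fluxes, propagation of per-pathway 95 percent
    confidence intervals to the portfolio interval by quadrature and by Monte
    Carlo, marginal-abatement-cost curves with price-constrained queries, and
    tabular reporting. Ships a synthetic-data module that generates toy
    gridded landscapes (ESRI ASCII layers) and pathway parameter tables so the
    full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
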