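Package: cigsim
Title: Simulation of a Cigarette Tax Reform and Industry Price-Setting in Brazil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric simulation of the Brazilian cigarette excise reform that
    replaces PIS/COFINS with a CBS charged on the highest national retail price
    per brand. Provides a per-pack tax engine (ad valorem and specific
    components, minimum-feasible-price and markup inversions), a seeded
    generator of synthetic smoker microdata with known price elasticities,
    two-part price-elasticity estimation (prevalence probit plus conditional
    log-log regression), calibration of the illicit market share to an
    aggregate revenue target, and three industry price-setting scenarios with
    elasticity-driven demand response and state-level revenue aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
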