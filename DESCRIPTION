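Package: seatrade
Title: Dietary Contaminant Exposure Through Interprovincial Seafood Trade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses human dietary exposure to persistent
    hydrophobic contaminants (such as short-chain chlorinated paraffins)
    carried through a national seafood trade network. Provides a seeded
    synthetic-world generator for coastal contaminant fields, species
    parameters and provincial supply/demand; a steady-state marine food-web
    bioaccumulation model; a doubly-constrained Leontief-Strout gravity model
    of interprovincial trade fitted by iterative proportional fitting;
    estimated-daily-intake (EDI) exposure assessment with trade and no-trade
    counterfactual scenarios and origin attribution; and a multiobjective
    transportation linear program that re-routes trade to jointly minimise
    shipping cost and population exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
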