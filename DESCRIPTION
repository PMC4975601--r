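Package: biocogs
Title: Cost-of-Goods Modelling and Uncertainty Analysis for Recombinant
    Protein Bioprocesses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An open, configuration-driven cost-of-goods (CoG/g) model for
    recombinant protein manufacture, built around a Pichia pastoris
    fermentation with aqueous two-phase extraction and
    ultrafiltration/diafiltration recovery. Provides flowsheet mass
    balances and batch scheduling, an annual cost engine with category and
    per-unit-operation breakdowns, demand sizing from market assumptions,
    one-at-a-time (tornado) scenario sensitivity analysis, joint Monte
    Carlo uncertainty analysis with triangular distributions and a
    moving-average stopping rule, linear sensitivity meta-models with a
    significance screen, and a calibration stage that pins the free cost
    constants to published anchor values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
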