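Package: pmmbimpact
Title: Budget Impact of Physician Withdrawal from the More Doctors Program
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic budget-impact analysis of the withdrawal of More
    Doctors for Brazil Program (Programa Mais Medicos para o Brasil, PMMB)
    physicians from municipalities of the state of Sao Paulo between January
    2019 and March 2022, from the perspective of Brazil's Unified Health
    System. Implements celetist (CLT) payroll arithmetic with progressive
    income-tax brackets and gross-up from a net wage target, per-cycle cost
    formulas for the federal and municipal payers built on Primary Care Floor
    transfers and physician scholarships, step-function monthly projection
    over the study horizon with counterfactual comparison and fixed-percentage
    sensitivity bounds, municipality stratification by program dependence and
    vulnerability indicator with replacement-eligibility rules and exit
    projections, and a seeded synthetic roster generator that reproduces the
    study's published marginals so the full pipeline is testable without any
    registry download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
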