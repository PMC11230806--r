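Package: perfuseCE
Title: Cost-Effectiveness and Budget Impact of Machine Perfusion for
    Expanded Criteria Donor Kidneys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time (annual-cycle) Markov cohort model of a deceased-donor
    kidney transplant waiting list, comparing universal static cold storage of
    recovered kidneys against selective hypothermic machine perfusion for
    expanded-criteria-donor (ECD) kidneys. Provides parameter containers with
    validation and YAML/JSON configuration round-trips, a synthetic-parameter
    generator for survival curves and probabilistic-sensitivity-analysis (PSA)
    distributions, the cohort engine itself, half-cycle-corrected costing with
    discounting, incremental cost-effectiveness ratios (ICER) with
    cost-effectiveness-plane classification, one-way deterministic sensitivity
    analysis with tornado ordering, second-order Monte Carlo PSA, and an
    undiscounted five-year budget impact analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
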