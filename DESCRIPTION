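Package: dialcea
Title: Cost-Utility Analysis of Dialysis Provision Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cost-utility analysis of hemodialysis (HD) versus continuous
    ambulatory peritoneal dialysis (CAPD) built around a three-state Markov
    cohort model (HD, CAPD, Death) with half-cycle correction and
    discounting. Provides Kaplan-Meier survival estimation and restricted
    mean life years from registry-style patient records, mid-year-population
    event rates with rate-to-probability conversion, incremental
    cost-effectiveness ratios with dominance analysis, net-monetary-benefit
    tornado diagrams, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a synthetic registry
    generator for end-to-end testing. Ships the published Malaysian
    Ministry of Health parameter set (costs, EQ-5D utilities, transition
    rates) as its default configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
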