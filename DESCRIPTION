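Package: tdabcost
Title: Time-Driven Activity-Based Costing and Equity Analysis for Health
    Service Encounters
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for time-driven activity-based costing (TDABC) of
    health-service encounters. Converts resource registries and practical
    capacities into capacity cost rates, turns per-patient step
    observations into encounter-level costs decomposed into human
    resources, space/equipment, indirects, and consumables, and summarizes
    service-line costs and their variation across facilities. An equity
    layer builds a principal-component household asset index and fits
    fixed-effects linear models of provider-patient time and cost. A
    seeded synthetic study generator with known ground-truth effects
    emulates a multi-facility HIV service delivery study so the full
    pipeline is testable without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
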