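Package: fortisim
Title: Simulation and Formula Models for Vitamin D Food Fortification Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning population-level vitamin D food fortification.
    Simulates per-individual fortified intake from food-vehicle consumption and
    per-100 g addition levels, searches a discrete grid of fortification plans
    under a hard tolerable-upper-intake-level (UL) constraint while minimizing
    the fraction of the population outside the recommended-intake-to-UL range,
    and implements the Flynn (ILSI) and Rasmussen (DFVR) safe-addition formulas
    with IOM-RDA unit algebra, including generators for safe-addition and
    maximum-supply tables and basket-level comparisons of the two approaches.
    Includes a seeded synthetic population generator with log-normal intake
    distributions calibrated to stated means and percentiles.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
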