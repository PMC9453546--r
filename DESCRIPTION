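Package: hydrotraits
Title: Drought Physiology Metrics and Hydraulic Trait Extraction for
    Pot-Desiccation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify isohydric and anisohydric stomatal behaviour
    from pot-desiccation (dry-down) experiments on woody crops. Implements
    the hydroscape area and the slope of the predawn versus midday water
    potential relationship (sigma), three-segment continuous piecewise
    regression of the water-potential curve with breakpoint estimation,
    Weibull xylem vulnerability-curve fitting with bootstrap confidence
    intervals for P50, pressure-volume curve trait extraction (osmotic
    potential at full turgor, turgor loss point, modulus of elasticity,
    capacitance), stomatal conductance decline models with the water
    potential at 90% stomatal closure, hydraulic safety margins, and a
    mechanistic synthetic dry-down generator with known ground truth for
    validating every stage of the analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
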