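Package: agrisoc
Title: Equivalent-Soil-Mass Carbon Stocks and Soil Multifunctionality for
    Tillage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for split-plot tillage field trials in
    wheat-maize double-cropping systems. Computes soil organic carbon
    storage on an equivalent-soil-mass basis (cumulative reference-mass
    correction for treatment-driven bulk density differences), a
    radar-area soil quality index from min-max scored physicochemical and
    biological indicators, and a z-score ecosystem multifunctionality
    index from soil enzyme activities. Includes factorial ANOVA with
    Fisher's LSD compact letter displays, per-layer correlation screens,
    random-forest permutation importance, and a reproducible synthetic
    trial generator emulating a two-factor split-plot design with depth
    profiles, plot-level random effects and configurable treatment
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
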