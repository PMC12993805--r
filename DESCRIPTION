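Package: peatfire
Title: Synthesis of Tropical Peatland Burning from Macro-Charcoal Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for synthesising macroscopic
    charcoal records from tropical peat cores into regional fire-history
    composites. Provides Monte-Carlo piecewise-linear age-depth ensembles,
    concentration-to-influx conversion, the proportional-relative-scaling
    (PRS) transform, binned and locally weighted smoothed bootstrap
    composite curves, at-most-one-change (AMOC) mean/variance change-point
    detection, twentieth-century change classification, and site-level
    statistics (group tests, ordination, correlation-screened regression).
    Includes a synthetic-data generator that emulates the structure of
    tropical peatland charcoal compilations so every stage can be exercised
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
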