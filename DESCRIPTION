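Package: redlinair
Title: Historical Redlining Scores and Longitudinal Air Pollution Trends
    for Urban Census Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the legacy of 1930s Home Owners' Loan Corporation
    (HOLC) residential security grading ("redlining") in present-day air
    pollution. Computes tract-level HOLC grade fractions and a continuous
    weighted redlining score by planar polygon overlay, aggregates gridded
    daily pollutant estimates (PM2.5, NO2) to tract-year annual means with
    area-proportional weights and robust outlier screening, summarises
    census and Social Vulnerability Index variables by redlining category
    with percent change over time, and fits linear mixed-effects trend
    models with category-by-year interactions, overall Wald tests, and
    Bonferroni-adjusted pairwise contrasts. A synthetic-city simulator with
    known ground truth (tract lattice, graded polygons, daily pollution
    grid, census tables) makes the whole pipeline testable without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    grDevices,
    jsonlite,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
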