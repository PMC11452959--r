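Package: ncdtrend
Title: Change-Point Trend Analysis and Global Target Assessment for
    Premature NCD Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing long-run trends in premature (ages 30-69)
    mortality from the four major noncommunicable diseases (cardiovascular
    disease, cancers, diabetes mellitus, chronic respiratory diseases).
    Builds crude 30-69 mortality rates per 100,000 from age-stratified
    death and population counts in Global Burden of Disease Results Tool
    exports, fits piecewise linear (segmented) trends with simultaneous
    level and slope changes at unknown change points under exact AR(1)
    maximum likelihood, selects the change-point configuration by AIC,
    forecasts rates to policy horizons with simulation-based intervals,
    computes the WHO 25x25 and SDG 3.4.1 target levels, and classifies the
    likelihood of target achievement into four categories. Includes a
    synthetic-data generator producing piecewise-linear rate series with
    autocorrelated noise and consistent age-stratified counts, a
    short-window sensitivity analysis, and table/figure reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
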