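Package: glequity
Title: Health Burden of Air Pollution and the Geographic Equity of Its Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the adult mortality burden attributable to long-term
    PM2.5 and ozone exposure on a population grid using nonlinear
    exposure-response curves with a theoretical minimum-risk exposure level,
    translates the burden into years of life lost and loss/gain of life
    expectancy, and measures the geographic equity of health benefits between
    policy stages with population-weighted Lorenz curves and the Gini index.
    Includes a seed-reproducible synthetic scenario generator emulating a
    two-stage national clean-air programme (spatially autocorrelated exposure
    fields, an aging population pyramid, subgroup baseline mortality,
    sublinear relative-risk curves with draw-level uncertainty) and Monte
    Carlo propagation of exposure-response uncertainty to empirical
    confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
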