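Package: frailpa
Title: Joint Analysis of Accelerometer-Measured Physical Activity and Frailty on Mortality and Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how device-measured physical activity interacts
    with deficit-accumulation frailty to shape all-cause mortality and residual
    life expectancy in middle-aged and older adults. Provides a synthetic
    UK-Biobank-like cohort generator with known ground truth (correlated
    activity exposures, 49-item frailty deficits, Gompertz survival), frailty-index
    scoring and classification, 30-second epoch aggregation into intensity-specific
    exposures with wear-validity rules, joint-group and restricted-cubic-spline Cox
    proportional-hazards modelling with additive (RERI) and multiplicative
    interaction measures, and hazard-ratio-and-prevalence-adjusted life tables
    with parametric-bootstrap confidence intervals, orchestrated by a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    splines,
    survival,
    MASS,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
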