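Package: hierfca
Title: Multi-Stage Floating Catchment Area Accessibility for Tiered Hospital Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures residents' spatial accessibility to a three-tier
    (primary / county / municipal) hospital system under a hierarchical
    diagnosis-and-treatment regime. Implements a multi-stage two-step
    floating catchment area (2SFCA) model with gravity distance decay,
    multi-factor hospital-selection weights built from hospital grade,
    scale and type, capacity-derived inter-tier referral rates, and
    three public-health-event scenarios. Includes a seeded synthetic
    study-region generator, scenario comparison summaries, four-class
    accessibility classification, per-tier contribution rates, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
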