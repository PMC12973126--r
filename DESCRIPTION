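Package: twinkit
Title: Classical Twin-Design Analysis of Infant Sleep, Settle, and Crying
    Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative-genetic analysis tools for the classical twin
    design applied to parent-reported infant sleep, settle, and crying
    measures. Fits univariate ACE, AE, CE, and E variance-component models
    with an optional sibling-interaction (rater-contrast) term by full
    information maximum likelihood, bivariate longitudinal Cholesky
    decompositions partitioning later-age variance into carried-over and
    age-unique genetic and environmental components, and
    population-averaged (GEE) regressions with cluster-robust standard
    errors for covariate screening and polygenic-score association.
    Includes a synthetic twin-cohort generator with the exact pair
    covariance structure the models assume, questionnaire preprocessing
    (duration parsing, corrected age, age-window exclusion, daylight
    exposure), and a config-driven pipeline reproducing the full analysis
    sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    sandwich
Config/testthat/edition: 3
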