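Package: apcie
Title: Age-Period-Cohort Modelling of Mortality Rates with the Intrinsic
    Estimator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits Poisson log-linear age-period-cohort (APC) models to
    Lexis tables of death counts and person-years using the intrinsic
    estimator: the minimum-norm solution obtained by constraining the
    coefficient vector to the orthogonal complement of the design
    matrix's one-dimensional null space. Includes validated rate-table
    input/output, the single-year-data-five-years-apart period sampling
    that keeps five-year birth cohorts identified, sum-to-zero effect
    expansion, deviance/AIC/BIC fit statistics, numerical
    differentiation of effect curves, relative-risk summaries, and a
    seeded synthetic Lexis-table generator with known ground truth for
    end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
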