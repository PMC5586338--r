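Package: phenolag
Title: Among-Population Asynchrony in Pollen Phenology from Ordinal
    Strobilus Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying asynchrony in pollen phenology among
    tree populations from repeated ordinal surveys of male strobilus
    development.  Provides a maximum-likelihood cumulative link
    (proportional-odds) model for 1-7 ordinal stage scores with calendar-day
    or thermal-time covariates, between-site and between-year time-lag
    estimation from model coefficients with cluster-bootstrap confidence
    intervals and a penalized significance rule, growing degree day
    computation, within-site rank-consistency analysis with Spearman
    correlations, and a synthetic survey generator for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
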