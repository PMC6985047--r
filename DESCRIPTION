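Package: agemix
Title: Two-Component Mixture Analysis of Age-at-Diagnosis Distributions
Version: 0.1.0
Authors@R:
    person("agemix", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits single-density and two-component mixture models (normal and
    semi-nonparametric polynomial-modified normal families) to age-at-diagnosis
    data within molecular strata of a case series, selects models by AIC with
    delta-AIC verdict rules, and reports early/late-onset modes and mixing
    proportions. Includes stratification utilities for estrogen-receptor
    percent positivity, ESR1 expression quartiles, PAM50 subtype and tumor
    characteristics, a synthetic-cohort generator for truncated bimodal age
    mixtures, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
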