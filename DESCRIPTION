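Package: painbn
Title: Constrained Bayesian Network Analysis of Chronic Pain Comorbidity Surveys
Version: 0.1.0
Authors@R:
    person("QBB", "Pain Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discrete Bayesian-network tools for survey cohorts of binary
    pain-location indicators and demographic covariates. Implements
    score-based structure learning (hill climbing with a decomposable BIC
    score under arc blacklists that keep demographic variables exogenous),
    maximum-likelihood conditional probability tables, exact
    conditional-probability queries by enumeration or variable elimination,
    and odds-ratio statistics with Woolf confidence intervals from 2x2
    contingency tables. A synthetic-cohort generator reproduces the
    marginal prevalences and pairwise associations of a 2,400-participant
    chronic-pain survey so that every pipeline stage is testable without
    access to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
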