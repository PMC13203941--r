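Package: grbtrends
Title: Global Gender-Role-Belief Trends and Their Demographic Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how population-level gender role beliefs (GRB)
    change over time and how demographic processes shape those changes.
    Implements a 0-100 composite GRB score from ordinal survey items, a
    hierarchical generalized additive trend model with poststratification on
    age-sex population counts, fixed-composition counterfactual decompositions
    of the global trend, a Bayesian measurement-error regression of population
    growth on national GRB, a within-between (hybrid) linear mixed model for
    completed fertility, and a Bayesian hierarchical four-parameter
    age-specific-fertility-rate model contrasting less and more egalitarian
    subpopulations. Ships a synthetic survey-microdata generator with recorded
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    tools,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
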