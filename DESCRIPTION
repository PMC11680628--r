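Package: quantmap
Title: Hierarchical Bayesian Modelling of Quantifier-to-Number Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating how people map natural-language quantifiers
    (few, fewer than half, many, more than half, most) onto proportions from
    truth-value judgment data. Implements a three-parameter hierarchical
    Bayesian logistic model decomposing each participant-quantifier response
    curve into a threshold, a vagueness scale, and a lapse-style response
    error; the preprocessing and exclusion rules for trial-level judgment
    data; a synthetic-cohort generator for validation by parameter recovery;
    and downstream individual-differences analyses (quantifier ordering
    tests, Ward clustering of thresholds, stepwise Wilks discriminant
    selection with LDA cross-validation, and cross-parameter correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
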