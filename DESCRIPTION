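Package: saeprev
Title: Multilevel Small-Area Estimation of Childhood Obesity Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based small-area estimation of childhood obesity
    prevalence at the census block-group level. Fits binomial multilevel
    logistic models with nested area random intercepts by Laplace-approximated
    maximum likelihood, post-stratifies predicted risks onto block-group
    demographic population cells, attaches Monte-Carlo 95% confidence
    intervals, aggregates to county, state and national levels, and validates
    model-based estimates against weighted direct survey estimates. Includes a
    synthetic-data generator that emulates a state-stratified national
    children's health survey over a nested state/county/zip/block-group
    geography so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
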