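Package: attritionr
Title: Analysis of Dropout Attrition in Item-Level Survey Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage framework for analyzing dropout attrition in
    web-based and item-level survey response data. Stage one visualizes
    attrition with bar charts and survival-type step curves, including
    skip-aware stacked charts and group comparisons. Stage two confirms
    significant attrition points by fitting a random-intercept logistic
    mixed model to each pair of sequential items (adaptive Gauss-Hermite
    quadrature) and transforming logit-scale estimates to differences in
    response proportions via the multivariate delta method. Stage three
    identifies respondent factors associated with dropout using
    contingency tests, the log-rank test on discrete dropout times, and
    Cox proportional-hazards regression with completers censored after
    the final item. A synthetic questionnaire-response simulator with
    known ground truth (discrete dropout hazards, subject-level frailty,
    sporadic skips, group effects) makes every stage testable without
    access to study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ggplot2,
    jsonlite,
    yaml,
    optparse,
    pracma
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
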