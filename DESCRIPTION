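Package: talentscreen
Title: Odds-Ratio Screening and Consensus Modelling of Athlete Development Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for holistic athlete-development analysis on small two-group
    cohorts. Continuous, Likert, training-volume and practice-proportion
    attributes are binarized at thresholds optimized over a 100-point grid,
    screened with small-sample-adjusted odds ratios and Fisher exact inference,
    and graded for importance by combining odds-ratio size with the
    true-positive rate. Four univariate feature-ranking procedures feed a
    top-20 consensus summary model, which is evaluated by leave-one-out
    cross-validated classification with naive Bayes, decision-tree, linear
    support-vector and nearest-neighbour classifiers. A synthetic-cohort
    generator with planted discriminative attributes makes every stage of the
    pipeline testable without access to confidential athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    rpart,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
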