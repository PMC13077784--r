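Package: snfchoice
Title: Discrete-Choice Analysis of Skilled Nursing Facility Referral Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying differential access to hospitals' preferred
    and high-quality skilled nursing facilities (SNFs) among patients with
    opioid use disorder (OUD). Provides a synthetic discharge-cohort
    generator with a known ground-truth choice process, hospital-year
    choice-set construction with volume-share preferred-network
    classification, greedy 1:k matching on hospital and discharge date,
    propensity-score estimation with inverse-probability weighting and
    quintile subclassification, hospital fixed-effect linear probability
    models, a McFadden conditional logit implemented from the likelihood up
    with OUD-by-attribute interactions and state-clustered sandwich
    covariance, counterfactual closest-SNF marginal effects, and a
    choice-set thinning check of the independence-of-irrelevant-alternatives
    assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
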