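Package: matemarket
Title: Agent-Based Models of Mate Preference Integration on Mating Markets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary agent-based models of human mating markets under
    alternative mate-preference-integration algorithms (Euclidean distance,
    cosine similarity, aspiration thresholds, linear, curvilinear, and cubic
    polynomial preference functions, plus random-pairing and
    preference-updating null models). Provides the Euclidean mate-value
    metric layer (preference fulfillment, overall mate value, ideal-partner
    mate value, partner mate value on a 0-10 scale), an out-of-sample
    model-comparison procedure that trains multilevel regressions on
    simulated markets and scores them against survey-style cohort data by
    RMSE and predicted-observed correlation, and a generator of synthetic
    cross-cultural survey cohorts with controlled effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
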