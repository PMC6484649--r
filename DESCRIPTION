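Package: harmforest
Title: Honest Causal Forest Discovery and Split-Sample Validation of
    Treatment-Harm Subgroups in Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery-and-validation pipeline for heterogeneous treatment
    effects in two-arm randomized trials with time-to-event outcomes.
    Selects a covariate-balanced 50/50 train/test split by entropy-weight
    scoring of many candidate random splits, grows an honest causal forest
    on quantile-discretized baseline covariates to flag subgroups with a
    positive (harmful) treatment-outcome association, distills the harm
    leaves into testable subgroup hypotheses, and validates them on the
    held-out half with site-stratified Cox proportional-hazards interaction
    models, a permutation-based false-discovery-rate estimate, observed
    event-frequency tables, and number-needed-to-harm. Includes mechanism
    analyses of longitudinal blood-pressure trajectories (mean arterial
    pressure contrasts) and a configurable synthetic-trial generator that
    emulates a SPRINT-like hypertension trial with an optional planted
    harmful subgroup, so the full pipeline is testable without access to
    restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
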