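Package: fowlplan
Title: Closed-Loop Feed Scheduling and Live-Weight Prediction for Cage-Reared Native Chickens
Version: 0.1.0
Authors@R:
    person("fowlplan", "developers", email = "fowlplan@example.org", role = c("aut", "cre"))
Description: Decision-support tools for precision feeding of cage-reared native
    chickens. Simulates Gompertz cage growth trajectories, daily-cyclic
    environmental sensor streams and intake profiles; builds leakage-safe model
    matrices (batch-wise temporal splits, blocked cross-validation folds,
    train-only imputation and min-max scaling); fits tabular regressors for
    daily live weight and interval total feed behind a pluggable contract, with
    Monte-Carlo permutation Shapley attribution; and steers a cage to a target
    live weight by a target date with a constrained, iteratively corrected daily
    ration plan, evaluated by interval feed conversion ratio and a partial-budget
    economic comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
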