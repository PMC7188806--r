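Package: ctdlearn
Title: Contextual Task-Demand Learning: Reinforcement-Learning Models and
    Pattern-Similarity Analyses on Synthetic Behavioral and Neural Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses experiments in which spatial contexts
    probabilistically cue task demands. Provides a synthetic-study generator
    (blocked 4-context by 2-task designs with 75/25 contingencies, delta-rule
    driven behavior, and multi-voxel activity patterns with planted context
    codes, task-demand reinstatement, and hippocampal-cortical coupling),
    temporal and contextual delta-rule learners with grid-search fitting,
    trial filtering and model-based accuracy/reaction-time regressions,
    event-level GLM estimation with multivariate noise normalization,
    cross-run Fisher-z pattern-similarity analyses with factorial congruency
    contrasts, block-level hippocampal-cortical coupling regressions, and
    two-stage group inference with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
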