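Package: spirotrans
Title: Multi-State Transitions of Spirometrically Defined COPD States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis of transitions between spirometrically
    defined chronic obstructive pulmonary disease (COPD) states in smokers.
    Classifies post-bronchodilator spirometry sessions into four ordinal
    states (normal, GOLD stage I, GOLD unclassified, GOLD stage II+) using
    NHANES-III reference equations with either the fixed 0.70 ratio or the
    lower-limit-of-normal criterion, builds discrete 18-month observation
    units from visit-level data, estimates a multi-state Markov-like
    transition-probability matrix, labels beneficial, resolution and harmful
    transitions, and fits cluster-robust logistic models for baseline
    predictors of beneficial transition. Includes a synthetic longitudinal
    cohort generator (latent lung-function trajectories with measurement
    noise, or a discrete Markov chain on states) for validation and power
    studies, plus end-to-end reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
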