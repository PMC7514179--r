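Package: posturePMA
Title: Principal Movement Analysis of Postural Control Under Dual-Tasking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes whole-body marker kinematics of quiet-stance trials
    into principal movements (PMs) by posture-space principal component
    analysis, computes per-component irregularity (lagged sample entropy of
    principal positions and accelerations) and control-tightness statistics
    (acceleration zero-crossing counts and inter-crossing timing variability),
    and tests dual-task and age-group effects with split-plot repeated-measures
    ANOVA including sphericity corrections, effect sizes, observed power and
    Sidak post-hoc contrasts. Includes a synthetic marker-trajectory cohort
    generator with known eigenstructure and planted condition effects so the
    full pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    zoo,
    car,
    nortest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
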