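Package: cuedapproach
Title: Peri-Event Analysis of Nucleus Accumbens Single-Unit Activity During
    Cued Approach
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for analyzing single-unit spike trains recorded
    during a Pavlovian cued-approach (CS) task: peri-event response
    classification via Poisson confidence bounds, binwise auROC encoding maps,
    Poisson generalized linear models of post-cue spike counts on
    approach-vigor covariates with a split-half-bootstrap
    population-equivalence F test, next-trial logistic reinforcement analysis,
    video locomotor-index thresholding, and behavioral endpoints (response
    ratios, discrimination index, pre/post-infusion epoch comparisons).
    Includes a synthetic-session generator with known ground truth so every
    stage can be exercised and calibrated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
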