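Package: oildrop
Title: Micelle-Likeness Hydrophobicity Profiles, Feedback-Loop Oscillators,
    and Specificity-Repetition Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three small analysis engines for quantitative cell-scale
    modelling.  (1) Fuzzy-oil-drop analysis of protein structures: theoretical
    (T), observed (O) and environment-modified (M) per-residue hydrophobicity
    distributions, the Kullback-Leibler order parameter RD, the environment
    parameter K, residue-level deficit/excess classification and an
    eliminate-and-recompute workflow.  (2) A discrete-time simulator for
    networks of up to three coupled negative-feedback units (threshold
    receptor plus effector) with oscillation measurement, reference-range
    checks and disturbance-propagation experiments.  (3) A planner for the
    trade-off between per-attempt specificity p and repetition count k,
    finding the minimum-energy plan that reaches a target success
    probability.  A synthetic-data module generates Gaussian point clouds
    with known micelle-likeness and loop-network fixtures so every engine is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
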