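Package: microvasc
Title: Microvascular Network Hemodynamics and Collateral Flow Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Steady-state Poiseuille blood flow on microvascular network
    graphs, with an inverse procedure that estimates unknown field-of-view
    boundary pressures from observed per-segment flow directions by
    simulated annealing. Ensembles of annealing restarts yield a
    per-segment uncertainty index (SD/mean of flow) that flags
    collateral-capable vessels; in-silico ablation tools recompute flow,
    detect reversals and test whether high-uncertainty segments are the
    ones that reverse. Includes descriptive diameter-remodeling statistics
    for longitudinal intravital measurements and a synthetic generator of
    hybrid tree-plus-arcade vascular networks with ground-truth boundary
    pressures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    Matrix,
    igraph,
    stats,
    utils,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
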