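Package: bnfit
Title: Learning Families of Boolean Networks from Perturbation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers families of Boolean networks from multi-perturbation
    phosphoproteomic (or any 0-1 normalized) time-series data constrained by a
    signed prior knowledge network. Candidate networks are enumerated from the
    sign-consistent clause space of the prior network, filtered by a meta-state
    over-approximation of reachability (support consistency), and ranked by an
    exact RMSE-optimal binary trace fit with automatic data-point correction.
    Optimal networks are then certified by explicit-state model checking of
    nested reachability, separating true-positive networks (which reproduce
    every binarized trajectory exactly) from false positives admitted by the
    over-approximation. Includes family-level analytics (hyper-edge frequency
    aggregation, Jaccard similarity, downstream-set TPR/FPR and AUROC, RMSE
    ratios, random-data validation), a synthetic benchmark generator, MIDAS and
    SIF readers/writers, and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
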