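Package: isobolr
Title: Isobolographic Synergy Analysis for Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loewe-additivity (isobolographic) synergy analysis for two-agent
    cytotoxicity experiments, built around plate-reader viability assays.
    Normalizes raw absorbances to percent effect, interpolates effective doses
    (ED_E) with a shape-preserving piecewise-cubic interpolant, attaches
    bootstrap confidence intervals, tests constancy of the potency ratio with a
    G-test, draws additivity isoboles with confidence envelopes, classifies
    combinations (synergistic, additive-consistent, antagonistic-consistent,
    inconclusive), and escalates the analysis effect level when the observed
    combination effect significantly exceeds 50 percent. Companion tools
    simulate plate assays and xenograft tumor growth with known ground truth,
    and compare in-vivo treatment groups (caliper volumes, t-tests, one-way
    ANOVA with Bonferroni-adjusted post-hoc comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
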