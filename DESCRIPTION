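Package: combind
Title: Drug-Combination Synergy, Xenograft Survival and Expression-Response
    Analysis for Preclinical Oncology Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for preclinical drug-combination
    studies in leukemia models. Fits the median-effect (Chou-Talalay) model to
    monotherapy dose-response data and scores drug-pair synergy by the
    combination index under Loewe additivity, for constant-ratio and
    checkerboard designs with per-sample and cohort summaries. Converts
    xenograft tumor-volume trajectories into regression-based time-to-endpoint
    values and analyses them with Kaplan-Meier curves and log-rank tests.
    Classifies combinatorial gene-expression responses into eight mutually
    exclusive fold-change categories and runs gene-set enrichment analysis
    with gene-set permutation FDR. A synthetic-data module generates every
    input with known ground truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
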