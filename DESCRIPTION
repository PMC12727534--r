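Package: photoflux
Title: Fibre Photometry Preprocessing, Peri-Event Analysis and Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-channel fibre-photometry recordings (465 nm sensor
    signal plus 405 nm isosbestic reference): isosbestic least-squares motion
    correction and dF/F computation, protocol-driven peri-event extraction and
    per-trial z-scoring, per-animal window summaries (means, binned traces,
    AUC), and the group statistics commonly attached to such analyses
    (pooled and Welch t-tests, Wilcoxon rank-sum with exact enumeration,
    balanced two-way ANOVA with Fisher's LSD post hoc). Includes a seeded
    simulator of two-channel cohorts with event-locked transients,
    multi-exponential bleaching, shared motion artifact and channel noise,
    providing ground truth for end-to-end validation, plus scalar metabolic
    phenotype indices (HOMA-IR, odour and diet preference, normalized latency,
    lean-mass-corrected energy expenditure).
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
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
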