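Package: ferroscore
Title: Relative Ferroptosis Level Scoring and Survival Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a per-sample relative ferroptosis level (RFL) from
    driver and suppressor gene signatures using single-sample gene set
    enrichment (ssGSEA), stratifies cohorts by an optimized RFL cutoff for
    Kaplan-Meier / log-rank survival analysis, screens for RFL-correlated
    genes across cohorts with recurrence and Jaccard-overlap summaries, and
    builds centered Cox proportional-hazards risk scores. Ships a synthetic
    cohort generator that emulates the latent-activity structure of bulk
    expression with proportional-hazards survival, treatment-shift
    experiments, and single-cell pseudobulk inputs, so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
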