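Package: lupsmacua
Title: Cost-Utility Cohort Models for 177Lu-PSMA-617 Radioligand Therapy in mCRPC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-inhomogeneous Markov cohort state-transition models for the
    cost-utility analysis of 177Lu-PSMA-617 radioligand therapy (PRLT) in
    metastatic castration-resistant prostate cancer, from the German statutory
    health insurance perspective. Provides parametric survival distributions
    with piecewise (knotted) stitching and per-cycle transition probabilities,
    reconstruction of pseudo individual patient data from digitized
    Kaplan-Meier curves with numbers at risk, a generic cohort engine with
    tunnel states, life-table within-cycle correction and discounted
    cost/QALY accrual, incremental cost-effectiveness comparison, and
    deterministic, probabilistic and scenario sensitivity analyses. Ships the
    base-case parameter tables for a third-line comparison of PRLT plus
    standard of care versus standard of care alone (Model I) and a second-line
    comparison of PRLT versus cabazitaxel with mixed third-line treatment
    (Model II), plus synthetic-data generators so the whole chain is testable
    without access to trial or claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
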