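Package: ehrpheno
Title: Phenotyping Disease Incidence and Progression from Multi-Source
    Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A modular pipeline for time-to-event phenotyping of disease
    incidence and progression from linked electronic health record (EHR)
    sources shaped like the UK Biobank releases: clinical codelist curation
    over Read v2/CTV3/ICD-10/OPCS4 terminologies (keyword search, hierarchy
    expansion, forward mapping, usage filtering, annotation-driven
    refinement), consolidation of dated clinical events across assessment,
    hospital, death and primary-care tables, longitudinal biomarker curation
    (CKD-EPI eGFR, urine albumin-to-creatinine ratio, albuminuria and
    prolonged-low-eGFR event detection, landmark-window summaries),
    prospective cohort construction with explicit exclusion and censoring
    rules, baseline covariate assembly (Charlson index, MET activity, ISCED
    education), and a landmark survival analysis: multiple imputation by
    chained equations, pooled stepwise Cox selection with forced base
    covariates, 2:1 train/validation risk prediction, AUC and median-split
    Kaplan-Meier evaluation. A synthetic data module generates all inputs
    with planted ground truth so every stage is testable without access to
    restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
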