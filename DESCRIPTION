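Package: recoex
Title: Seed-Anchored Gene Co-Expression Networks and Survival Screening
    for Breast Cancer Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds seed-gene-anchored Spearman co-expression networks from
    multi-cohort microarray expression data, compares networks across
    phenotype strata (lymph-node status, recurrence) to surface novel
    co-expressed genes, screens those genes with node-adjusted Cox
    proportional-hazards regression, and collapses tightly co-expressed gene
    sets into a standardized first-principal-component "immune index" with
    dichotomized prognostic models and predicted relapse-free survival
    curves. Includes cross-cohort moment harmonization to a reference
    cohort, a synthetic multi-cohort survival-data generator with a planted
    co-expressed block for end-to-end testing, and network export to GraphML
    and JSON node-link formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
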