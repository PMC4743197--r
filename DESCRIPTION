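Package: wesdx
Title: Diagnostic Exome Variant Prioritization for Microcephaly Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a diagnostic whole-exome variant-prioritization
    workflow for Mendelian cohorts: a depth / population-frequency /
    run-control / phenotype-panel filter cascade, sequential inheritance-model
    candidate generation (autosomal recessive homozygous and compound
    heterozygous, autosomal dominant, X-linked, de novo assessment), a
    rule-based causality classifier with a known-pathogenic fallback path,
    SNP-array runs-of-homozygosity and sib-pair shared-haplotype mapping, and
    cohort-level diagnostic-yield reporting. Ships a deterministic synthetic
    cohort generator that emulates a 35-family intellectual-disability with
    microcephaly study, with a machine-readable truth ledger so every stage
    of the pipeline can be verified end to end without access to patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
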