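#!/usr/bin/env Rscript
# Step 6 - cohort report.
#
# End-to-end pipeline over the on-disk bundle (exactly what a re-analysis
# of real data in the same layout would run) and the cohort summary:
# diagnostic yield, diagnosed patients, inheritance breakdown, distinct
# causal genes, phenotype descriptives.

suppressPackageStartupMessages(library(wesdx))

res <- run_pipeline("scratch/cohort", cascade_config())
stopifnot(res$ok)

report <- res$report
print(report)
jsonlite::write_json(
  list(n_families = report$n_families,
       n_patients = report$n_patients,
       n_diagnosed_families = report$n_diagnosed_families,
       n_diagnosed_patients = report$n_diagnosed_patients,
       diagnosed_families = report$diagnosed_families,
       yield_percent = report$yield_percent,
       model_breakdown = as.list(report$model_breakdown),
       distinct_causal_genes = report$distinct_causal_genes,
       phenotype_summary = report$phenotype_summary),
  "results/cohort_report.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("report written to results/cohort_report.json")
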