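#!/usr/bin/env Rscript
# Step 4 - causality classification.
#
# Full per-family processing (cascade, models, known-pathogenic fallback,
# evidence, segregation, classification) and the verdict table. A family
# counts as diagnosed when it has at least one causative verdict.

suppressPackageStartupMessages({library(wesdx); library(dplyr)})

bundle <- read_cohort("scratch/cohort")
res <- run_pipeline(bundle, cascade_config())

verdicts_table(res$verdicts, "results/verdicts.tsv")
diagnosed <- res$verdicts |>
  filter(verdict == "causative", rank == 1) |>
  select(family_id, model, gene, de_novo_status, segregation)
jsonlite::write_json(diagnosed, "results/diagnosed_families.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf("verdicts for %d candidates across %d families",
                nrow(res$verdicts), length(unique(res$verdicts$family_id))))
message(sprintf("diagnosed families: %d", nrow(diagnosed)))
print(as.data.frame(diagnosed))
message("written to results/verdicts.tsv and results/diagnosed_families.json")
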