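#!/usr/bin/env Rscript
# Step 1 - simulate the study cohort.
#
# Builds the 35-family synthetic microcephaly cohort (38 patients, three
# sib-pairs, six consanguineous families) with the ten causal genotypes
# embedded in their designated families, and writes the on-disk bundle
# (PED, phenotype/panel/lookup TSVs, per-family VCFs, control alleles,
# Sanger relative genotypes, SNP-array tracks, truth ledger).

suppressPackageStartupMessages(library(wesdx))

seed <- as.integer(Sys.getenv("WESDX_SEED", "1"))
out_dir <- "scratch/cohort"

bundle <- generate_cohort(cohort_config(seed = seed))
unlink(out_dir, recursive = TRUE)
write_cohort(bundle, out_dir)

truth <- bundle$truth$causal
message(sprintf("cohort seed %d: %d families, %d patients, %d variant records",
                seed, length(unique(bundle$pedigree$family_id)),
                sum(bundle$phenotypes$affected), nrow(bundle$variants)))
message(sprintf("embedded causal genotypes: %d (%s)", nrow(truth),
                paste(sort(unique(truth$gene)), collapse = ", ")))
message("bundle written to ", out_dir)
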