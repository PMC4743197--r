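#!/usr/bin/env Rscript
# Step 3 - sequential inheritance models.
#
# Runs the cascade per family, merges Sanger relative genotypes, and
# enumerates model candidates in the sequential order autosomal recessive
# (homozygous, compound heterozygous) -> autosomal dominant -> X-linked,
# writing one row per candidate.

suppressPackageStartupMessages({library(wesdx); library(dplyr); library(purrr)})

bundle <- read_cohort("scratch/cohort")
cfg <- cascade_config()

cands <- list()
for (fam in unique(bundle$variants$family_id)) {
  v <- bundle$variants |> filter(family_id == fam) |> select(-family_id)
  fam_ped <- bundle$pedigree |> filter(family_id == fam)
  affected <- intersect(fam_ped$individual_id[fam_ped$affected],
                        unique(unlist(lapply(v$gt, names))))
  res <- apply_cascade(v, affected, bundle$panel, bundle$controls, cfg)
  matched <- merge_relative_genotypes(res$matched, bundle$relatives,
                                      family_id = fam)
  cands[[fam]] <- apply_sequential_models(matched, fam_ped, fam)
}
candidates <- bind_rows(cands)
flat <- candidates |>
  mutate(variant_keys = map_chr(keys, paste, collapse = ";")) |>
  select(family_id, model, priority, gene, variant_keys, de_novo_status,
         phase_known, segregation_notes)
write_simple_tsv(flat, "results/model_candidates.tsv")

message(sprintf("%d candidates in %d families", nrow(flat),
                length(unique(flat$family_id))))
print(count(flat, model))
message("written to results/model_candidates.tsv")
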