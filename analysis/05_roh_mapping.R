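#!/usr/bin/env Rscript
# Step 5 - homozygosity and shared-haplotype mapping.
#
# Scans the SNP-array tracks: single-patient runs of homozygosity for the
# consanguineous recessive diagnosis, and the three sib-pair sharing modes
# (shared homozygous alleles, shared genotype combination, at least one
# shared allele). Intervals go out as BED (0-based half-open) plus TSV.

suppressPackageStartupMessages({library(wesdx); library(dplyr)})

tracks <- read_snp_tracks("scratch/cohort/snp_tracks.tsv")
truth <- jsonlite::read_json("scratch/cohort/truth.json")

intervals <- list()
# single-patient ROH on every single-sample track
singles <- vapply(Filter(function(x) x$mode == "single_roh", truth$roh),
                  function(x) x$sample, "")
for (s in singles) {
  tr <- tracks |> filter(sample == s)
  iv <- detect_roh_single(tr)
  if (nrow(iv) > 0) iv$sample <- s
  intervals[[paste0("roh_", s)]] <- iv
  message(sprintf("%s: %d ROH, longest %.2f Mb", s, nrow(iv),
                  max(iv$length_bp) / 1e6))
}
# sib-pair sharing in the planted mode of each pair
pairs <- Filter(function(x) x$mode != "single_roh", truth$roh)
for (p in pairs) {
  sibs <- strsplit(p$sample, ",")[[1]]
  a <- tracks |> filter(sample == sibs[1])
  b <- tracks |> filter(sample == sibs[2])
  iv <- switch(p$mode,
               sibs_shared_hom = shared_homozygous_sibs(a, b),
               recessive_shared = shared_haplotype_recessive(a, b),
               dominant_shared = shared_haplotype_dominant(a, b))
  if (nrow(iv) > 0) iv$sample <- p$sample
  intervals[[paste0(p$mode, "_", sibs[1])]] <- iv
  top <- iv[which.max(iv$length_bp), ]
  message(sprintf("%s (%s): %d intervals, longest %.2f Mb at %s:%d-%d",
                  p$sample, p$mode, nrow(iv), top$length_bp / 1e6,
                  top$chrom, top$start, top$end))
}
all_iv <- bind_rows(intervals)
write_intervals(all_iv, bed_path = "results/roh_intervals.bed",
                tsv_path = "results/roh_intervals.tsv")
message("intervals written to results/roh_intervals.{bed,tsv}")
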