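#' Full prioritization pipeline
#'
#' Per family: filter cascade over the family's annotated variants (depth,
#' population frequency, same-run controls, phenotype panel), candidate
#' generation under the sequential inheritance models on the matched set
#' (with Sanger relative genotypes merged in), the known-pathogenic
#' fallback over the unmatched set, evidence assessment, segregation check
#' and causality classification. Families are independent, so the cohort
#' result does not depend on processing order; a family whose input fails
#' to load is marked failed and the remaining families are still processed.
#'
#' @name pipeline
NULL

#' Process one family
#'
#' @param variants family variant table (as read from the family VCF).
#' @param family_id family identifier.
#' @param bundle cohort bundle (pedigree, panel, known-pathogenic table,
#'   controls, relatives, phenotypes).
#' @param config a [cascade_config()].
#' @return list with `verdicts`, `trace`, `candidates`.
#' @export
process_family <- function(variants, family_id, bundle,
                           config = cascade_config()) {
  ped <- bundle$pedigree
  fam_ped <- ped[ped$family_id == family_id, ]
  sequenced <- intersect(unique(unlist(map(variants$gt, names))),
                         fam_ped$individual_id)
  affected <- intersect(sequenced,
                        fam_ped$individual_id[fam_ped$affected])
  cascade <- apply_cascade(variants, affected, bundle$panel,
                           bundle$controls, config)
  matched <- merge_relative_genotypes(cascade$matched, bundle$relatives,
                                      family_id = family_id)
  candidates <- apply_sequential_models(matched, fam_ped, family_id)

  fb_variants <- hgmd_fallback(cascade$unmatched, bundle$known_pathogenic)
  if (nrow(fb_variants) > 0) {
    fb_variants <- merge_relative_genotypes(fb_variants, bundle$relatives,
                                            family_id = family_id)
    fb <- apply_sequential_models(fb_variants, fam_ped, family_id)
    if (nrow(fb) > 0) {
      fb$fallback <- TRUE
      candidates <- bind_rows(candidates, fb)
    }
  }

  patient_hpo <- unique(unlist(
    bundle$phenotypes$hpo_terms[bundle$phenotypes$family_id == family_id]))
  evidence <- assess_evidence(candidates, bundle$panel, patient_hpo,
                              bundle$known_pathogenic, max_af = config$max_af)
  segregation <- map_chr(seq_len(nrow(candidates)), function(i) {
    check_segregation(candidates[i, ], fam_ped)
  })
  verdicts <- classify(candidates, evidence, segregation)
  list(verdicts = verdicts, trace = cascade$trace, candidates = candidates)
}

#' Run the pipeline over a cohort
#'
#' @param cohort either a `cohort_bundle` (from [generate_cohort()] /
#'   [read_cohort()]) or a directory in the on-disk bundle layout.
#' @param config a [cascade_config()].
#' @return list with `verdicts` (all families), `report`
#'   ([summarize_cohort()]), `traces` (named per family), `failed_families`
#'   (character vector), and `ok` (`TRUE` when no family failed).
#' @export
run_pipeline <- function(cohort, config = cascade_config()) {
  from_dir <- is.character(cohort)
  failed <- character(0)
  if (from_dir) {
    dir <- cohort
    bundle <- list(
      pedigree = read_ped(file.path(dir, "pedigree.ped")),
      phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv")),
      panel = read_gene_panel(file.path(dir, "panel.tsv")),
      known_pathogenic = read_known_pathogenic(file.path(dir, "known_pathogenic.tsv")),
      controls = read_tsv_quiet(file.path(dir, "controls.tsv"),
                                col_types = readr::cols(
                                  sample = "c", chrom = "c", pos = "i",
                                  ref = "c", alt = "c")),
      relatives = {
        p <- file.path(dir, "relatives.tsv")
        if (file.exists(p)) read_tsv_quiet(p, col_types = readr::cols(
          family_id = "c", individual_id = "c", chrom = "c", pos = "i",
          ref = "c", alt = "c", gt = "c")) else NULL
      }
    )
    fam_variants <- list()
    for (path in sort(list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                                 full.names = TRUE))) {
      fam <- sub("\\.vcf$", "", basename(path))
      v <- tryCatch(read_vcf(path, bundle$pedigree), error = function(e) e)
      if (inherits(v, "error")) {
        warn(paste0("family ", fam, " failed to load: ", conditionMessage(v)))
        failed <- c(failed, fam)
      } else {
        fam_variants[[fam]] <- v
      }
    }
  } else {
    bundle <- cohort
    fam_variants <- map(
      split(bundle$variants, bundle$variants$family_id),
      function(v) select(v, -"family_id"))
  }

  fams <- unique(bundle$pedigree$family_id)
  verdicts <- list()
  traces <- list()
  for (fam in intersect(fams, names(fam_variants))) {
    res <- process_family(fam_variants[[fam]], fam, bundle, config)
    verdicts[[fam]] <- res$verdicts
    traces[[fam]] <- res$trace
  }
  verdicts <- bind_rows(verdicts)
  report <- summarize_cohort(verdicts, bundle$pedigree, bundle$phenotypes)
  report$failed_families <- failed
  list(verdicts = verdicts, report = report, traces = traces,
       failed_families = failed, ok = length(failed) == 0)
}

#' Export verdicts as a flat TSV
#'
#' @param verdicts verdict tibble from [classify()] / [run_pipeline()].
#' @param path output path (or `NULL` to just get the flat tibble).
#' @return the flat tibble, invisibly when written.
#' @export
verdicts_table <- function(verdicts, path = NULL) {
  flat <- verdicts |>
    mutate(variant_keys = map_chr(.data$keys, paste, collapse = ";")) |>
    select("family_id", "rank", "verdict", "model", "gene", "variant_keys",
           "de_novo_status", "phase_known", "fallback", "gene_disease_match",
           "deleteriousness", "population_absent", "segregation",
           "sanger_confirmed", "segregation_notes")
  if (!is.null(path)) {
    readr::write_tsv(flat, path, progress = FALSE)
    return(invisible(flat))
  }
  flat
}
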