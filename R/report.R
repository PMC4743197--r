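#' Cohort-level diagnostic summary
#'
#' Aggregates per-family causality verdicts into the cohort report:
#' diagnostic yield (percent of families with at least one causative
#' verdict, rounded to the nearest integer, half away from zero), diagnosed
#' patients (affected study patients — individuals present in the phenotype
#' table — in diagnosed families, so an affected sib-pair contributes two),
#' the inheritance-mode breakdown of the top-ranked causative verdict per
#' family, the distinct causal genes, and phenotype descriptives (mean age
#' to the nearest year; mean head-circumference Z-score to one decimal over
#' the available values; families suspected of a recessive disorder —
#' consanguineous parents or two or more affected sibs — with percent).
#'
#' @param verdicts verdict tibble from [classify()] covering all families
#'   (families with no candidates simply contribute no rows).
#' @param pedigree cohort pedigree.
#' @param phenotypes cohort phenotype table.
#' @return a `cohort_report` list.
#' @export
summarize_cohort <- function(verdicts, pedigree, phenotypes) {
  fams <- unique(pedigree$family_id)
  if (nrow(verdicts) > 0) {
    missing <- setdiff(unique(verdicts$family_id), fams)
    if (length(missing) > 0) {
      abort(paste0("verdict family absent from pedigree: ",
                   paste(missing, collapse = ", ")))
    }
  }
  n_families <- length(fams)
  patients <- phenotypes$individual_id[phenotypes$affected]
  n_patients <- length(patients)

  causative <- verdicts[verdicts$verdict == "causative", , drop = FALSE]
  diagnosed_fams <- sort(unique(causative$family_id))
  n_diag_fam <- length(diagnosed_fams)
  n_diag_pat <- sum(phenotypes$affected &
                      phenotypes$family_id %in% diagnosed_fams)

  # inheritance mode of the top-ranked causative verdict per family
  top <- causative |>
    group_by(.data$family_id) |>
    slice_min(.data$rank, n = 1, with_ties = FALSE) |>
    ungroup()
  modes <- vapply(top$model, candidate_mode, "")
  breakdown <- c(AR = sum(modes == "AR"), AD = sum(modes == "AD"),
                 XL = sum(modes == "XL"))
  genes <- sort(unique(causative$gene))

  suspected <- pedigree |>
    group_by(.data$family_id) |>
    summarise(
      consang = any(.data$consanguineous_parents & .data$affected),
      multi_affected = sum(.data$affected &
                             .data$individual_id %in% patients) >= 2,
      .groups = "drop") |>
    mutate(suspected = .data$consang | .data$multi_affected)
  n_suspected <- sum(suspected$suspected)

  ages <- phenotypes$age_years
  ofc <- phenotypes$ofc_z[!is.na(phenotypes$ofc_z)]

  structure(list(
    n_families = n_families,
    n_patients = n_patients,
    n_diagnosed_families = n_diag_fam,
    n_diagnosed_patients = n_diag_pat,
    diagnosed_families = diagnosed_fams,
    yield_percent = as.integer(round_half_away(100 * n_diag_fam / n_families)),
    model_breakdown = breakdown,
    distinct_causal_genes = list(n = length(genes), genes = genes),
    phenotype_summary = list(
      mean_age_years = as.integer(round_half_away(mean(ages))),
      mean_ofc_z = round_half_away(mean(ofc), 1),
      n_ofc_available = length(ofc),
      n_suspected_recessive = n_suspected,
      suspected_recessive_percent =
        as.integer(round_half_away(100 * n_suspected / n_families))
    )
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort: %d families, %d patients\n", x$n_families, x$n_patients))
  cat(sprintf("Diagnosed: %d families (%d%% yield), %d patients\n",
              x$n_diagnosed_families, x$yield_percent, x$n_diagnosed_patients))
  cat(sprintf("Inheritance: AR=%d AD=%d XL=%d\n",
              x$model_breakdown[["AR"]], x$model_breakdown[["AD"]],
              x$model_breakdown[["XL"]]))
  cat(sprintf("Causal genes (%d): %s\n", x$distinct_causal_genes$n,
              paste(x$distinct_causal_genes$genes, collapse = ", ")))
  ps <- x$phenotype_summary
  cat(sprintf("Phenotypes: mean age %d y; mean OFC Z %.1f SD (n=%d); suspected recessive %d (%d%%)\n",
              ps$mean_age_years, ps$mean_ofc_z, ps$n_ofc_available,
              ps$n_suspected_recessive, ps$suspected_recessive_percent))
  invisible(x)
}
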