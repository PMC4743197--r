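#' Causality classification of model candidates
#'
#' A candidate is designated **causative** only if all of the following
#' hold; otherwise it remains a **candidate**, or is **excluded** outright
#' when segregation contradicts the model:
#'
#' * the variant(s) are Sanger-confirmed,
#' * the gene is known to cause a disorder whose clinical features are
#'   consistent with the patient's phenotype (operationalized as >= 1 shared
#'   HPO term between patient terms and panel-disorder terms) under the
#'   candidate's inheritance mode,
#' * deleteriousness evidence: reported pathogenic in the literature/lookup
#'   database, truncating or splice-site consequence, or predicted
#'   deleterious by at least three prediction algorithms,
#' * absent from, or rare (at most the cascade frequency threshold) in, all
#'   consulted population databases including EVS and ExAC,
#' * familial segregation, where testable, is consistent with the mode of
#'   inheritance.
#'
#' For compound-heterozygous candidates the deleteriousness and
#' population-absence requirements must hold for *both* alleles.
#'
#' @name causality
NULL

# per-variant deleteriousness class; returns list(class, k, rank)
deleteriousness_of <- function(v, known_keys) {
  known <- isTRUE(v$known_pathogenic) || variant_key(v) %in% known_keys
  if (known) return(list(class = "known_pathogenic", k = NA_integer_, rank = 3L))
  if (v$consequence %in% truncating_classes()) {
    return(list(class = "truncating_or_splice", k = NA_integer_, rank = 2L))
  }
  k <- sum(unlist(v$pred[[1]]) == "deleterious")
  if (k > 0) {
    list(class = paste0("predicted_deleterious_", k), k = as.integer(k), rank = 1L)
  } else {
    list(class = "insufficient", k = 0L, rank = 0L)
  }
}

deleterious_sufficient <- function(del) {
  del$rank >= 2L || (!is.na(del$k) && del$k >= 3L)
}

population_absent_of <- function(v, max_af = 0.02) {
  freqs <- v$pop_freqs[[1]]
  length(freqs) == 0 || all(freqs <= max_af)
}

candidate_mode <- function(model) {
  c(AR_hom = "AR", AR_comphet = "AR", AD = "AD", XL = "XL")[[model]]
}

#' Assess the evidence behind candidates
#'
#' @param candidates candidate tibble from [apply_sequential_models()].
#' @param panel gene panel ([read_gene_panel()]).
#' @param patient_hpo character vector of the patient's (or affected
#'   members' pooled) HPO terms.
#' @param known_pathogenic known-pathogenic lookup table (may be `NULL`).
#' @param max_af frequency ceiling below which a database observation does
#'   not count against population absence (the cascade threshold; a reported
#'   pathogenic allele at 0.13 % remains classifiable causative).
#' @return evidence tibble, one row per candidate: `gene_disease_match`,
#'   `deleteriousness`, `k_deleterious`, `deleteriousness_rank`,
#'   `population_absent`, `sanger_confirmed`.
#' @export
assess_evidence <- function(candidates, panel, patient_hpo,
                            known_pathogenic = NULL, max_af = 0.02) {
  known_keys <- if (!is.null(known_pathogenic) && nrow(known_pathogenic) > 0) {
    variant_key(known_pathogenic)
  } else character(0)
  known_disorder <- if (length(known_keys) > 0 && "disorder" %in% names(known_pathogenic)) {
    setNames(!is.na(known_pathogenic$disorder) & nzchar(known_pathogenic$disorder),
             known_keys)
  } else setNames(logical(0), character(0))

  rows <- map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    vs <- cand$variants[[1]]
    dels <- map(seq_len(nrow(vs)), function(j) deleteriousness_of(vs[j, ], known_keys))
    weakest <- dels[[which.min(map_dbl(dels, function(d) {
      d$rank + ifelse(is.na(d$k), 0, pmin(d$k, 9) / 10)
    }))]]
    pop_ok <- all(map_lgl(seq_len(nrow(vs)), function(j) {
      population_absent_of(vs[j, ], max_af)
    }))
    if (isTRUE(cand$fallback)) {
      # phenotype consistency judged from the lookup's disorder annotation
      match <- any(unname(known_disorder[variant_key(vs)]), na.rm = TRUE)
    } else {
      entries <- panel[panel$gene == cand$gene, ]
      match <- FALSE
      for (e in seq_len(nrow(entries))) {
        shared <- length(intersect(entries$hpo_terms[[e]], patient_hpo)) > 0
        mode_ok <- candidate_mode(cand$model) %in% entries$inheritance_modes[[e]]
        if (shared && mode_ok) { match <- TRUE; break }
      }
    }
    tibble(
      gene_disease_match = match,
      deleteriousness = weakest$class,
      k_deleterious = weakest$k,
      deleteriousness_rank = weakest$rank,
      deleterious_sufficient = all(map_lgl(dels, deleterious_sufficient)),
      population_absent = pop_ok,
      sanger_confirmed = all(vs$sanger_confirmed)
    )
  })
  if (length(rows) == 0) {
    tibble(gene_disease_match = logical(), deleteriousness = character(),
           k_deleterious = integer(), deleteriousness_rank = integer(),
           deleterious_sufficient = logical(), population_absent = logical(),
           sanger_confirmed = logical())
  } else bind_rows(rows)
}

#' Check familial segregation of a candidate
#'
#' Evaluates every genotyped relative (parents of affected members and
#' unaffected members) against the candidate's inheritance model: `"yes"`
#' when all informative relatives are compatible, `"no"` on any
#' incompatibility, `"untestable"` when no informative relative is
#' genotyped.
#'
#' @param candidate one row of a candidate tibble.
#' @param pedigree pedigree table.
#' @return `"yes"`, `"no"` or `"untestable"`.
#' @export
check_segregation <- function(candidate, pedigree) {
  roles <- family_roles(pedigree, candidate$family_id)
  vs <- candidate$variants[[1]]
  model <- candidate$model
  parents <- affected_parents(roles)
  informative <- 0L

  compat <- TRUE
  for (j in seq_len(nrow(vs))) {
    gt <- vs$gt[[j]]
    par_gen <- parents[is_genotyped(gt, parents)]
    unaff <- setdiff(roles$unaffected, parents)
    unaff_gen <- unaff[is_genotyped(gt, unaff)]
    informative <- informative + length(par_gen) + length(unaff_gen)
    if (model == "AR_hom") {
      if (!all(gt_of(gt, par_gen) %in% "het")) compat <- FALSE
      if (any(gt_of(gt, unaff_gen) %in% "hom_alt")) compat <- FALSE
    } else if (model == "AD") {
      if (any(gt_of(gt, c(par_gen[!par_gen %in% roles$affected], unaff_gen))
              %in% carrier_codes())) {
        # carried by an unaffected relative: segregation violation
        compat <- FALSE
      }
    } else if (model == "XL") {
      males <- c(par_gen, unaff_gen)[roles$sex_of[c(par_gen, unaff_gen)] == "male"]
      females <- setdiff(c(par_gen, unaff_gen), males)
      unaff_males <- setdiff(males, roles$affected)
      if (any(gt_of(gt, unaff_males) %in% c("hemi", "hom_alt"))) compat <- FALSE
      if (any(gt_of(gt, setdiff(females, roles$affected)) %in% "hom_alt")) compat <- FALSE
    }
  }
  if (model == "AR_comphet") {
    phase <- comphet_phase(vs$gt[[1]], vs$gt[[2]], roles)
    if (identical(phase, "cis")) compat <- FALSE
    if (identical(phase, "trans")) informative <- informative + 1L
    unaff <- setdiff(roles$unaffected, parents)
    both <- map_lgl(unaff, function(id) {
      all(map_lgl(seq_len(nrow(vs)), function(j) {
        is_genotyped(vs$gt[[j]], id) && gt_of(vs$gt[[j]], id) %in% carrier_codes()
      }))
    })
    if (any(both)) compat <- FALSE
  }
  if (!compat) return("no")
  if (informative == 0L) return("untestable")
  "yes"
}

#' Pure verdict rule
#'
#' Deterministic and monotone in the evidence: strengthening any field
#' (segregation no -> untestable -> yes, FALSE -> TRUE flags, higher
#' deleteriousness) never demotes the verdict.
#'
#' @param gene_disease_match,population_absent,sanger_confirmed logicals.
#' @param deleterious_sufficient logical: known pathogenic, truncating or
#'   splice, or >= 3 deleterious predictions (for all alleles of the
#'   candidate).
#' @param segregation `"yes"`, `"no"` or `"untestable"`.
#' @return `"causative"`, `"candidate"` or `"excluded"`.
#' @export
verdict_rule <- function(gene_disease_match, deleterious_sufficient,
                         population_absent, segregation, sanger_confirmed) {
  if (segregation == "no") return("excluded")
  if (gene_disease_match && sanger_confirmed && population_absent &&
      deleterious_sufficient) {
    return("causative")
  }
  "candidate"
}

#' Classify candidates and rank them per family
#'
#' Ranking within a family: causative before candidate before excluded;
#' then model order (AR before AD/XL, with homozygous-ALT dominant
#' candidates down-ranked); ties broken by deleteriousness class then
#' lexicographic gene symbol.
#'
#' @param candidates candidate tibble.
#' @param evidence evidence tibble from [assess_evidence()] (row-aligned).
#' @param segregation character vector of [check_segregation()] results,
#'   row-aligned with `candidates`.
#' @return verdicts tibble: candidates + evidence + `segregation`,
#'   `verdict`, `rank` (per family).
#' @export
classify <- function(candidates, evidence, segregation) {
  out <- bind_cols(candidates, evidence)
  out$segregation <- segregation
  out$verdict <- map_chr(seq_len(nrow(out)), function(i) {
    verdict_rule(out$gene_disease_match[i], out$deleterious_sufficient[i],
                 out$population_absent[i], out$segregation[i],
                 out$sanger_confirmed[i])
  })
  verdict_order <- c(causative = 1L, candidate = 2L, excluded = 3L)
  out |>
    mutate(
      eff_priority = .data$priority + ifelse(.data$hom_alt_ad, 10L, 0L),
      v_ord = verdict_order[.data$verdict]
    ) |>
    group_by(.data$family_id) |>
    arrange(.data$v_ord, .data$eff_priority, -.data$deleteriousness_rank,
            .data$gene, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    select(-"v_ord", -"eff_priority")
}

#' Known-pathogenic fallback for phenotype-unmatched variants
#'
#' Variants that failed the phenotype-panel match but are present in the
#' known-pathogenic lookup re-enter candidate generation, flagged
#' `fallback`; their phenotype consistency is then judged from the lookup's
#' disorder annotation instead of the panel.
#'
#' @param unmatched unmatched variant table from the cascade.
#' @param known_pathogenic lookup table ([read_known_pathogenic()]).
#' @return subset of `unmatched` present in the lookup.
#' @export
hgmd_fallback <- function(unmatched, known_pathogenic) {
  if (is.null(known_pathogenic) || nrow(known_pathogenic) == 0 ||
      nrow(unmatched) == 0) {
    return(unmatched[0, ])
  }
  unmatched[variant_key(unmatched) %in% variant_key(known_pathogenic), ]
}
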