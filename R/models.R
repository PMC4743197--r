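#' Sequential Mendelian inheritance models
#'
#' Candidate generation per family over phenotype-matched variants, in the
#' order recessive first, then dominant, then X-linked:
#'
#' * **AR_hom** — autosomal variant homozygous ALT in every genotyped
#'   affected member, heterozygous in each genotyped parent, not homozygous
#'   ALT in any genotyped unaffected member.
#' * **AR_comphet** — two heterozygous variants in one autosomal gene in
#'   every genotyped affected member. When both parents are genotyped for
#'   both variants the pair must be in trans (one allele transmitted by each
#'   parent); pairs with ungenotyped parents are kept but flagged
#'   `phase_known = FALSE`; pairs demonstrably in cis (both alleles in one
#'   parent) are rejected.
#' * **AD** — autosomal variant carried (het, or hom_alt, which is
#'   down-ranked) by every genotyped affected member and absent from every
#'   genotyped unaffected member; de novo status assessed from parental
#'   genotypes: both parents genotyped negative = `confirmed`, one parent
#'   untested = `probable`, no parent genotyped = `unknown`, carried by an
#'   affected parent = `inherited`.
#' * **XL** — X-chromosomal variant, het (or hom_alt) in genotyped affected
#'   females, hemizygous in genotyped affected males, never hemizygous in a
#'   genotyped unaffected male; de novo status as in AD.
#'
#' Missing genotypes are never treated as reference: an ungenotyped
#' individual simply cannot veto (or support) a candidate. Mitochondrial and
#' Y variants are outside model scope (they reach the classifier only
#' through the known-pathogenic fallback).
#'
#' @name inheritance-models
NULL

model_priority <- c(AR_hom = 1L, AR_comphet = 2L, AD = 3L, XL = 4L)

empty_candidates <- function() {
  tibble(family_id = character(), model = character(), gene = character(),
         keys = list(), variants = list(), de_novo_status = character(),
         phase_known = logical(), hom_alt_ad = logical(),
         fallback = logical(), priority = integer(),
         segregation_notes = character())
}

new_candidate <- function(family_id, model, gene, variant_rows,
                          de_novo_status = NA_character_,
                          phase_known = NA, hom_alt_ad = FALSE,
                          fallback = FALSE, notes = "") {
  tibble(family_id = family_id, model = model, gene = gene,
         keys = list(variant_key(variant_rows)),
         variants = list(variant_rows),
         de_novo_status = de_novo_status,
         phase_known = phase_known, hom_alt_ad = hom_alt_ad,
         fallback = fallback, priority = model_priority[[model]],
         segregation_notes = notes)
}

# family bookkeeping shared by the model generators
family_roles <- function(pedigree, family_id) {
  fam <- pedigree[pedigree$family_id == family_id, ]
  list(
    members = fam,
    affected = fam$individual_id[fam$affected],
    unaffected = fam$individual_id[!fam$affected],
    father_of = setNames(fam$father_id, fam$individual_id),
    mother_of = setNames(fam$mother_id, fam$individual_id),
    sex_of = setNames(fam$sex, fam$individual_id)
  )
}

# all genotyped members of `ids` have genotype in `allowed`; at least one does
all_genotyped_in <- function(gt_map, ids, allowed, require_one = TRUE) {
  genotyped <- ids[is_genotyped(gt_map, ids)]
  if (require_one && length(genotyped) == 0) return(FALSE)
  all(gt_of(gt_map, genotyped) %in% allowed)
}

note_genotypes <- function(gt_map, ids) {
  genotyped <- ids[is_genotyped(gt_map, ids)]
  if (length(genotyped) == 0) return("")
  paste(paste0(genotyped, ":", gt_of(gt_map, genotyped)), collapse = ";")
}

# parents (with pedigree links) of the affected members, deduplicated
affected_parents <- function(roles) {
  unique(stats::na.omit(c(roles$father_of[roles$affected],
                          roles$mother_of[roles$affected])))
}

#' @rdname inheritance-models
#' @param variants variant table for one family (relative genotypes merged
#'   via [merge_relative_genotypes()] if available).
#' @param pedigree pedigree table.
#' @param family_id family to evaluate; defaults to the single family in
#'   `pedigree` if unambiguous.
#' @return a candidate tibble (possibly empty) with one row per candidate.
#' @export
candidates_recessive <- function(variants, pedigree, family_id = NULL) {
  family_id <- family_id %||% unique(pedigree$family_id)
  stopifnot(length(family_id) == 1)
  roles <- family_roles(pedigree, family_id)
  out <- list()

  auto <- variants[is_autosome(variants$chrom), ]
  # AR_hom
  for (i in seq_len(nrow(auto))) {
    gt <- auto$gt[[i]]
    if (!all_genotyped_in(gt, roles$affected, "hom_alt")) next
    parents <- affected_parents(roles)
    par_gen <- parents[is_genotyped(gt, parents)]
    if (!all(gt_of(gt, par_gen) %in% "het")) next
    unaff_gen <- roles$unaffected[is_genotyped(gt, roles$unaffected)]
    if (any(gt_of(gt, unaff_gen) %in% "hom_alt")) next
    out[[length(out) + 1]] <- new_candidate(
      family_id, "AR_hom", auto$gene[i], auto[i, ],
      notes = note_genotypes(gt, c(parents, roles$unaffected)))
  }

  # AR_comphet: pairs of het variants per gene
  genes <- unique(auto$gene[nzchar(auto$gene)])
  for (g in genes) {
    rows <- which(auto$gene == g)
    if (length(rows) < 2) next
    het_ok <- vapply(rows, function(i) {
      all_genotyped_in(auto$gt[[i]], roles$affected, "het")
    }, logical(1))
    rows <- rows[het_ok]
    if (length(rows) < 2) next
    for (a in seq_along(rows)) {
      for (b in seq_along(rows)) {
        if (a >= b) next
        i <- rows[a]; j <- rows[b]
        # canonical allele order, so candidate identity is input-order free
        ord <- order(auto$pos[c(i, j)], auto$ref[c(i, j)], auto$alt[c(i, j)])
        ij <- c(i, j)[ord]
        i <- ij[1]; j <- ij[2]
        phase <- comphet_phase(auto$gt[[i]], auto$gt[[j]], roles)
        if (identical(phase, "cis")) next
        out[[length(out) + 1]] <- new_candidate(
          family_id, "AR_comphet", g, auto[c(i, j), ],
          phase_known = identical(phase, "trans"),
          notes = paste0(
            note_genotypes(auto$gt[[i]], affected_parents(roles)), "|",
            note_genotypes(auto$gt[[j]], affected_parents(roles))))
      }
    }
  }
  if (length(out) == 0) empty_candidates() else bind_rows(out)
}

# phase of a candidate pair from parental genotypes:
# "trans" (one allele per parent), "cis" (both alleles traceable to one
# parent, or one allele in neither genotyped parent), or "unknown"
comphet_phase <- function(gt_a, gt_b, roles) {
  for (child in roles$affected) {
    fa <- roles$father_of[[child]]
    mo <- roles$mother_of[[child]]
    if (is.na(fa) || is.na(mo)) next
    both_gen <- all(is_genotyped(gt_a, c(fa, mo))) &&
      all(is_genotyped(gt_b, c(fa, mo)))
    if (!both_gen) next
    fa_a <- gt_of(gt_a, fa) %in% carrier_codes()
    mo_a <- gt_of(gt_a, mo) %in% carrier_codes()
    fa_b <- gt_of(gt_b, fa) %in% carrier_codes()
    mo_b <- gt_of(gt_b, mo) %in% carrier_codes()
    trans <- (fa_a && !mo_a && mo_b && !fa_b) ||
      (mo_a && !fa_a && fa_b && !mo_b)
    if (trans) return("trans")
    return("cis")
  }
  "unknown"
}

# shared de novo assessment for dominant-type candidates
assess_de_novo <- function(gt, roles) {
  # transmission from an affected carrier parent wins
  for (child in roles$affected) {
    for (p in stats::na.omit(c(roles$father_of[[child]], roles$mother_of[[child]]))) {
      if (p %in% roles$affected && is_genotyped(gt, p) &&
          gt_of(gt, p) %in% carrier_codes()) {
        return("inherited")
      }
    }
  }
  best <- -1L
  for (child in roles$affected) {
    parents <- stats::na.omit(c(roles$father_of[[child]], roles$mother_of[[child]]))
    if (length(parents) == 0) next
    tested <- sum(is_genotyped(gt, parents) &
                    !(gt_of(gt, parents) %in% carrier_codes()))
    best <- max(best, as.integer(tested))
  }
  if (best >= 2) "confirmed" else if (best == 1) "probable" else "unknown"
}

#' @rdname inheritance-models
#' @export
candidates_dominant <- function(variants, pedigree, family_id = NULL) {
  family_id <- family_id %||% unique(pedigree$family_id)
  stopifnot(length(family_id) == 1)
  roles <- family_roles(pedigree, family_id)
  out <- list()
  auto <- variants[is_autosome(variants$chrom), ]
  for (i in seq_len(nrow(auto))) {
    gt <- auto$gt[[i]]
    if (!all_genotyped_in(gt, roles$affected, c("het", "hom_alt"))) next
    unaff_gen <- roles$unaffected[is_genotyped(gt, roles$unaffected)]
    if (any(gt_of(gt, unaff_gen) %in% carrier_codes())) next
    out[[length(out) + 1]] <- new_candidate(
      family_id, "AD", auto$gene[i], auto[i, ],
      de_novo_status = assess_de_novo(gt, roles),
      hom_alt_ad = any(gt_of(gt, roles$affected) %in% "hom_alt", na.rm = TRUE),
      notes = note_genotypes(gt, c(affected_parents(roles), roles$unaffected)))
  }
  if (length(out) == 0) empty_candidates() else bind_rows(out)
}

#' @rdname inheritance-models
#' @export
candidates_xlinked <- function(variants, pedigree, family_id = NULL) {
  family_id <- family_id %||% unique(pedigree$family_id)
  stopifnot(length(family_id) == 1)
  roles <- family_roles(pedigree, family_id)
  out <- list()
  xv <- variants[is_chrx(variants$chrom), ]
  for (i in seq_len(nrow(xv))) {
    gt <- xv$gt[[i]]
    aff_gen <- roles$affected[is_genotyped(gt, roles$affected)]
    if (length(aff_gen) == 0) next
    ok <- vapply(aff_gen, function(id) {
      g <- gt_of(gt, id)
      if (roles$sex_of[[id]] == "male") g == "hemi" else g %in% c("het", "hom_alt")
    }, logical(1))
    if (!all(ok)) next
    unaff_males <- roles$unaffected[roles$sex_of[roles$unaffected] == "male"]
    unaff_gen <- unaff_males[is_genotyped(gt, unaff_males)]
    if (any(gt_of(gt, unaff_gen) %in% c("hemi", "hom_alt"))) next
    out[[length(out) + 1]] <- new_candidate(
      family_id, "XL", xv$gene[i], xv[i, ],
      de_novo_status = assess_de_novo(gt, roles),
      notes = note_genotypes(gt, c(affected_parents(roles), roles$unaffected)))
  }
  if (length(out) == 0) empty_candidates() else bind_rows(out)
}

#' @rdname inheritance-models
#' @return `apply_sequential_models()` returns all candidates of all models
#'   ordered by model priority (AR_hom, AR_comphet, AD, XL); nothing is
#'   silently truncated — the downstream causality classifier decides.
#' @export
apply_sequential_models <- function(variants, pedigree, family_id = NULL) {
  bind_rows(
    candidates_recessive(variants, pedigree, family_id),
    candidates_dominant(variants, pedigree, family_id),
    candidates_xlinked(variants, pedigree, family_id)
  ) |>
    arrange(.data$priority)
}
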