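#' Annotated variant tables
#'
#' The central container of the pipeline is a tibble with one row per
#' biallelic variant record (one ALT allele per row; multi-allelic sites are
#' decomposed on read). Scalar columns carry the site annotation, list
#' columns carry per-sample and per-database maps:
#'
#' * `chrom`, `pos` (1-based), `ref`, `alt`, `gene` (may be `""`),
#'   `consequence` (one of [consequence_classes()]),
#' * `pop_freqs`: named numeric vector per row, database -> allele frequency
#'   in \[0, 1\]; a database absent from the map means *not observed there*,
#'   which is deliberately distinct from frequency 0,
#' * `pred`: named character vector per row, prediction algorithm ->
#'   `"deleterious"`, `"tolerated"` or `"unknown"`,
#' * `known_pathogenic`, `sanger_confirmed`: logicals,
#' * `gt`: named character vector per row, sample -> genotype in
#'   [genotype_codes()],
#' * `dp`: named numeric vector per row, sample -> read depth (`NA` allowed,
#'   treated as depth 0 by the read-depth filter).
#'
#' `validate_variants()` checks the structural invariants (positions >= 1,
#' `ref != alt`, frequencies in \[0, 1\], legal genotype and consequence
#' codes) and returns the table invisibly, aborting on the first violation.
#'
#' @param variants a variant table.
#' @return `validate_variants()` returns `variants` invisibly.
#' @name variant-table
NULL

#' Legal consequence classes
#' @return character vector of consequence class codes.
#' @export
consequence_classes <- function() {
  c("frameshift", "stop_gained", "splice_site", "missense", "synonymous",
    "inframe_indel", "other")
}

#' Consequence classes counted as truncating or splice-disrupting
#' @return character vector.
#' @export
truncating_classes <- function() {
  c("frameshift", "stop_gained", "splice_site")
}

#' Legal genotype codes
#'
#' `hemi` denotes a hemizygous ALT call (male X outside any configured
#' pseudoautosomal region); hemizygous reference calls are coded `hom_ref`.
#'
#' @return character vector of genotype codes.
#' @export
genotype_codes <- function() {
  c("hom_ref", "het", "hom_alt", "hemi", "no_call")
}

# genotypes that carry >= 1 copy of the ALT allele
carrier_codes <- function() c("het", "hom_alt", "hemi")

#' @rdname variant-table
#' @export
validate_variants <- function(variants) {
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "pop_freqs", "pred", "known_pathogenic", "sanger_confirmed",
                "gt", "dp")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    abort(paste0("variant table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$pos < 1)) abort("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  bad_csq <- setdiff(unique(variants$consequence), consequence_classes())
  if (length(bad_csq) > 0) {
    abort(paste0("unknown consequence class: ", paste(bad_csq, collapse = ", ")))
  }
  freqs <- unlist(variants$pop_freqs, use.names = FALSE)
  if (length(freqs) > 0 && (any(freqs < 0) || any(freqs > 1))) {
    abort("population allele frequencies must lie in [0, 1]")
  }
  gts <- unlist(variants$gt, use.names = FALSE)
  bad_gt <- setdiff(unique(gts), genotype_codes())
  if (length(bad_gt) > 0) {
    abort(paste0("unknown genotype code: ", paste(bad_gt, collapse = ", ")))
  }
  invisible(variants)
}

#' Build a variant table row-wise (used by the simulator and tests)
#'
#' @param ... scalar fields per variant; see [variant-table] for the schema.
#'   `pop_freqs`, `pred`, `gt`, `dp` accept a (possibly empty) named vector.
#' @return one-row variant table.
#' @keywords internal
#' @export
variant_row <- function(chrom, pos, ref, alt, gene = "", consequence = "other",
                        pop_freqs = numeric(), pred = character(),
                        known_pathogenic = FALSE, sanger_confirmed = FALSE,
                        gt = character(), dp = numeric()) {
  tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), consequence = as.character(consequence),
    pop_freqs = list(pop_freqs), pred = list(pred),
    known_pathogenic = known_pathogenic, sanger_confirmed = sanger_confirmed,
    gt = list(gt), dp = list(dp)
  )
}

# sample -> genotype lookup with "no_call" for unknown samples;
# returns NA_character_ for samples not genotyped at all (not in the map)
gt_of <- function(gt_map, sample) {
  out <- unname(gt_map[sample])
  out[is.na(out)] <- NA_character_
  out
}

# TRUE if the individual is genotyped (present in the map with a real call)
is_genotyped <- function(gt_map, sample) {
  !is.na(gt_of(gt_map, sample)) & gt_of(gt_map, sample) != "no_call"
}

#' Merge relative (Sanger) genotypes into a variant table
#'
#' Segregation genotypes obtained for additional family members (typically
#' Sanger follow-up of parents or unaffected relatives) are supplied as a
#' long table with columns `family_id`, `individual_id`, `chrom`, `pos`,
#' `ref`, `alt`, `gt`. For every matching variant record the individual is
#' added to (or overwritten in) that row's genotype map, so the inheritance
#' models and segregation checks see one uniform genotype source.
#'
#' @param variants variant table (with a `family_id` column or all one family).
#' @param relatives long genotype table as described; may be `NULL` or empty.
#' @param family_id family the variants belong to, used when `variants` has
#'   no `family_id` column.
#' @return the variant table with augmented `gt` maps.
#' @export
merge_relative_genotypes <- function(variants, relatives, family_id = NULL) {
  if (is.null(relatives) || nrow(relatives) == 0 || nrow(variants) == 0) {
    return(variants)
  }
  fam <- if ("family_id" %in% names(variants)) variants$family_id else
    rep(family_id %||% NA_character_, nrow(variants))
  vkey <- paste(fam, variant_key(variants), sep = "|")
  rkey <- paste(relatives$family_id,
                variant_key(relatives$chrom, relatives$pos,
                            relatives$ref, relatives$alt), sep = "|")
  idx <- split(seq_len(nrow(relatives)), rkey)
  variants$gt <- map2(variants$gt, vkey, function(g, k) {
    rows <- idx[[k]]
    if (is.null(rows)) return(g)
    g[relatives$individual_id[rows]] <- relatives$gt[rows]
    g
  })
  variants
}
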