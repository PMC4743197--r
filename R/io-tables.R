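#' Tabular readers for pedigrees, phenotypes, panels and lookups
#'
#' All tables are tab-separated UTF-8 with a mandatory header row. HPO term
#' sets are serialized as comma-separated `HP:NNNNNNN` identifiers;
#' inheritance-mode sets as comma-separated subsets of `AR`, `AD`, `XL`.
#'
#' @name table-io
NULL

read_tsv_quiet <- function(path, ...) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         lazy = FALSE, ...)
  # drop reader bookkeeping attributes so equal inputs give identical tibbles
  attr(tbl, "spec") <- NULL
  attr(tbl, "problems") <- NULL
  tbl
}

require_columns <- function(tbl, cols, what) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(what, " table lacks mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl
}

split_terms <- function(x) {
  map(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    trimws(strsplit(s, "[,;]")[[1]])
  })
}

check_hpo_syntax <- function(terms, what) {
  flat <- unlist(terms, use.names = FALSE)
  bad <- flat[!grepl("^HP:[0-9]{7}$", flat)]
  if (length(bad) > 0) {
    abort(paste0(what, ": malformed HPO identifier(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
}

#' Read a pedigree (PED dialect)
#'
#' Six standard whitespace-separated columns (family, individual, father,
#' mother, sex, affection) plus an optional seventh `consang` 0/1 column.
#' Sex codes 1 = male, 2 = female; affection 2 = affected, 1/0 = unaffected.
#' `0` as a parent id means unknown. The pedigree is validated: parent
#' references must resolve within the family (or be unknown) and no
#' individual may be its own ancestor.
#'
#' @param path PED file path.
#' @return tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (NA = unknown), `sex`, `affected`, `consanguineous_parents`.
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "", comment.char = "#",
                           colClasses = "character")
  if (ncol(raw) < 6) abort("PED file must have >= 6 columns")
  sex_code <- raw[[5]]
  bad_sex <- setdiff(unique(sex_code), c("1", "2"))
  if (length(bad_sex) > 0) {
    abort(paste0("unknown PED sex code: ", paste(bad_sex, collapse = ", ")))
  }
  ped <- tibble(
    family_id = raw[[1]],
    individual_id = raw[[2]],
    father_id = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = ifelse(sex_code == "1", "male", "female"),
    affected = raw[[6]] == "2",
    consanguineous_parents = if (ncol(raw) >= 7) raw[[7]] == "1" else FALSE
  )
  validate_pedigree(ped)
}

#' Validate pedigree structure
#'
#' @param ped pedigree tibble as returned by [read_ped()].
#' @return `ped`, invisibly on success (returned visibly for chaining).
#' @export
validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$individual_id)) {
    abort("duplicate individual ids in pedigree")
  }
  for (fam in unique(ped$family_id)) {
    members <- ped[ped$family_id == fam, ]
    parents <- stats::na.omit(c(members$father_id, members$mother_id))
    unresolved <- setdiff(parents, members$individual_id)
    if (length(unresolved) > 0) {
      abort(paste0("family ", fam, ": parent id(s) not in family: ",
                   paste(unique(unresolved), collapse = ", ")))
    }
    # walk up from each individual; revisiting it means a parentage cycle
    parent_of <- setNames(
      map2(members$father_id, members$mother_id, function(f, m) {
        stats::na.omit(c(f, m))
      }),
      members$individual_id)
    for (id in members$individual_id) {
      frontier <- parent_of[[id]]
      seen <- character(0)
      while (length(frontier) > 0) {
        if (id %in% frontier) {
          abort(paste0("family ", fam, ": ", id, " is its own ancestor"))
        }
        seen <- union(seen, frontier)
        frontier <- setdiff(
          unique(unlist(parent_of[as.character(frontier)], use.names = FALSE)),
          seen)
      }
    }
  }
  ped
}

#' Read the phenotype table
#'
#' Columns: `family_id`, `individual_id`, `age_years`, `sex`, `ofc_z`
#' (occipitofrontal head-circumference Z-score in SD units, may be empty =
#' not available), `consanguineous_parents` (0/1), `affected` (0/1),
#' `hpo_terms` (comma-separated HPO identifiers).
#'
#' @param path TSV path.
#' @return tibble with `hpo_terms` as a list column of character vectors.
#' @export
read_phenotypes <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(
    family_id = "c", individual_id = "c", age_years = "d", sex = "c",
    ofc_z = "d", consanguineous_parents = "l", affected = "l",
    hpo_terms = "c"))
  require_columns(tbl, c("family_id", "individual_id", "age_years", "sex",
                         "ofc_z", "consanguineous_parents", "affected",
                         "hpo_terms"), "phenotype")
  if (any(!is.finite(tbl$ofc_z) & !is.na(tbl$ofc_z))) {
    abort("ofc_z must be finite when present")
  }
  tbl$hpo_terms <- split_terms(tbl$hpo_terms)
  check_hpo_syntax(tbl$hpo_terms, "phenotype table")
  tbl
}

#' Read a gene panel
#'
#' Columns: `gene`, `hpo_terms` (comma-separated), `disorder`,
#' `inheritance_modes` (comma-separated subset of AR, AD, XL). Each
#' (gene, disorder) pair must be unique and carry at least one mode.
#'
#' @param path TSV path.
#' @return tibble with list columns `hpo_terms` and `inheritance_modes`.
#' @export
read_gene_panel <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  require_columns(tbl, c("gene", "hpo_terms", "disorder", "inheritance_modes"),
                  "gene panel")
  if (anyDuplicated(paste(tbl$gene, tbl$disorder))) {
    abort("duplicate (gene, disorder) row in gene panel")
  }
  tbl$hpo_terms <- split_terms(tbl$hpo_terms)
  check_hpo_syntax(tbl$hpo_terms, "gene panel")
  tbl$inheritance_modes <- split_terms(tbl$inheritance_modes)
  bad <- setdiff(unlist(tbl$inheritance_modes), c("AR", "AD", "XL"))
  if (length(bad) > 0) {
    abort(paste0("unknown inheritance mode: ", paste(bad, collapse = ", ")))
  }
  if (any(lengths(tbl$inheritance_modes) == 0)) {
    abort("every panel entry needs >= 1 inheritance mode")
  }
  tbl
}

#' Read a known-pathogenic lookup table
#'
#' Stand-in for a curated pathogenic-variant database: allele-level keys
#' (`chrom`, `pos`, `ref`, `alt`) with optional `gene`, `protein_change` and
#' `disorder` annotation. Keys must be unique.
#'
#' @param path TSV path.
#' @return tibble of known-pathogenic entries.
#' @export
read_known_pathogenic <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", .default = "c"))
  require_columns(tbl, c("chrom", "pos", "ref", "alt"), "known-pathogenic")
  if (anyDuplicated(variant_key(tbl))) {
    abort("duplicate variant key in known-pathogenic table")
  }
  tbl
}

#' Read SNP-array genotype tracks
#'
#' Columns: `sample`, `chrom`, `pos`, `genotype` in `AA`, `AB`, `BB`,
#' `no_call`. Positions must be strictly increasing within each
#' sample/chromosome track.
#'
#' @param path TSV path.
#' @return tibble of genotype records.
#' @export
read_snp_tracks <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(
    sample = "c", chrom = "c", pos = "i", genotype = "c"))
  require_columns(tbl, c("sample", "chrom", "pos", "genotype"), "SNP track")
  validate_snp_track(tbl)
}

#' @rdname read_snp_tracks
#' @param track SNP-track tibble to validate.
#' @export
validate_snp_track <- function(track) {
  bad <- setdiff(unique(track$genotype), c("AA", "AB", "BB", "no_call"))
  if (length(bad) > 0) {
    abort(paste0("SNP track: non-biallelic genotype code(s): ",
                 paste(bad, collapse = ", ")))
  }
  ord <- track |>
    group_by(.data$sample, .data$chrom) |>
    summarise(sorted = !is.unsorted(.data$pos, strictly = TRUE), .groups = "drop")
  if (any(!ord$sorted)) {
    abort("SNP track positions must be strictly increasing per sample/chromosome")
  }
  track
}

#' Write a pedigree as PED
#' @param ped pedigree tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ifelse(ped$sex == "male", "1", "2"),
    ifelse(ped$affected, "2", "1"),
    as.integer(ped$consanguineous_parents))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

join_terms <- function(x) vapply(x, paste, "", collapse = ",")

#' Writers for the remaining bundle tables
#'
#' Inverse of the corresponding readers; used by [write_cohort()].
#'
#' @param tbl the table to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @name table-writers
NULL

#' @rdname table-writers
#' @export
write_phenotypes <- function(tbl, path) {
  out <- tbl
  out$hpo_terms <- join_terms(out$hpo_terms)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname table-writers
#' @export
write_gene_panel <- function(tbl, path) {
  out <- tbl
  out$hpo_terms <- join_terms(out$hpo_terms)
  out$inheritance_modes <- join_terms(out$inheritance_modes)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname table-writers
#' @export
write_simple_tsv <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
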