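#' VCF input and output for annotated exome variants
#'
#' The pipeline consumes per-family VCF v4.2 files whose annotations live in
#' INFO/FORMAT fields under fixed keys:
#'
#' * `GENE` (gene symbol, site-level), `CSQCLASS` (consequence class, one
#'   value per ALT allele),
#' * `AF_<db>` for `db` in dbSNP, 1000G, Seattle, GoNL, EVS, ExAC (allele
#'   frequency per ALT allele; an absent key means the allele was not
#'   observed in that database),
#' * `PRED_<alg>` for SIFT, PolyPhen2, MutationTaster, AlignGVGD with values
#'   `D` (deleterious), `T` (tolerated), `U` (unknown),
#' * `KNOWN_PATH` and `SANGER` as 0/1 flags,
#' * FORMAT `GT` and `DP` per sample.
#'
#' Multi-allelic sites are decomposed into one record per ALT allele, with
#' the genotype re-expressed relative to the kept allele (any other ALT
#' allele counts as reference for that record). Male genotypes on the X
#' chromosome are normalized to `hemi` when they carry the ALT allele,
#' except inside pseudoautosomal regions if supplied.
#'
#' @name vcf-io
NULL

freq_databases <- function() c("dbSNP", "1000G", "Seattle", "GoNL", "EVS", "ExAC")
prediction_algorithms <- function() c("SIFT", "PolyPhen2", "MutationTaster", "AlignGVGD")

pred_to_code <- c(deleterious = "D", tolerated = "T", unknown = "U")
code_to_pred <- c(D = "deleterious", T = "tolerated", U = "unknown")

# parse one INFO string into a named list of raw values
parse_info <- function(info) {
  if (is.na(info) || info == "" || info == ".") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2) x[2] else "1")
  names(vals) <- vapply(kv, `[[`, "", 1)
  vals
}

# kth comma-separated element, recycling a single value across ALT alleles
nth_or_single <- function(value, k) {
  if (is.null(value)) return(NA_character_)
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  if (length(parts) == 1) parts else parts[k]
}

# re-express a raw GT string relative to ALT allele index k (1-based)
parse_gt <- function(gt_raw, k) {
  if (is.na(gt_raw) || gt_raw %in% c(".", "./.", ".|.")) return("no_call")
  alleles <- strsplit(gt_raw, "[/|]")[[1]]
  if (any(alleles == ".")) return("no_call")
  n_alt <- sum(alleles == as.character(k))
  if (length(alleles) == 1) {
    return(if (n_alt == 1) "hemi" else "hom_ref")
  }
  if (n_alt == 0) "hom_ref" else if (n_alt == length(alleles)) "hom_alt" else "het"
}

in_par <- function(pos, par_regions) {
  if (is.null(par_regions) || nrow(par_regions) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(par_regions))) {
    out <- out | (pos >= par_regions$start[i] & pos <= par_regions$end[i])
  }
  out
}

#' Read an annotated family VCF
#'
#' @param path path to a VCF v4.x file (see [vcf-io] for the expected keys).
#' @param pedigree pedigree table (see [read_ped()]); every sample in the VCF
#'   header must appear as an `individual_id`, otherwise a reconciliation
#'   error is raised.
#' @param par_regions optional data frame with `start`/`end` columns giving
#'   pseudoautosomal intervals on the X chromosome (1-based inclusive);
#'   default `NULL` treats the whole X as hemizygous in males.
#' @return a variant table ([variant-table]) with one row per ALT allele and
#'   attribute `samples` (VCF sample order).
#' @export
read_vcf <- function(path, pedigree = NULL, par_regions = NULL) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!startsWith(lines, "#"))
  for (i in body_idx) {
    nfield <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nfield < 10) {
      abort(paste0("malformed VCF record at line ", i, " of ", path,
                   " (", nfield, " fields, expected >= 10)"))
    }
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF ", path, ": ",
                                     conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(pedigree)) {
    unknown <- setdiff(samples, pedigree$individual_id)
    if (length(unknown) > 0) {
      abort(paste0("VCF sample(s) absent from pedigree: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  sex_of <- if (!is.null(pedigree)) {
    setNames(pedigree$sex, pedigree$individual_id)
  } else {
    setNames(character(0), character(0))
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    info <- parse_info(fix[i, "INFO"])
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    site_rows <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      csq <- nth_or_single(info[["CSQCLASS"]], k)
      if (is.na(csq)) csq <- "other"
      freqs <- numeric(0)
      for (db in freq_databases()) {
        raw <- nth_or_single(info[[paste0("AF_", db)]], k)
        if (!is.na(raw) && raw != ".") freqs[db] <- as.numeric(raw)
      }
      if (any(freqs < 0, na.rm = TRUE)) {
        abort(paste0("negative allele frequency at ", chrom, ":", pos))
      }
      preds <- character(0)
      for (alg in prediction_algorithms()) {
        raw <- info[[paste0("PRED_", alg)]]
        if (!is.null(raw) && raw %in% names(code_to_pred)) {
          preds[alg] <- unname(code_to_pred[raw])
        }
      }
      gts <- vapply(samples, function(s) parse_gt(gt_raw[i, s], k), "")
      if (is_chrx(chrom) && length(sex_of) > 0 && !in_par(pos, par_regions)) {
        males <- samples[!is.na(sex_of[samples]) & sex_of[samples] == "male"]
        carried <- males[gts[males] %in% carrier_codes()]
        gts[carried] <- "hemi"
      }
      dps <- setNames(as.numeric(dp_raw[i, samples]), samples)
      site_rows[[k]] <- variant_row(
        chrom = chrom, pos = pos, ref = fix[i, "REF"], alt = alts[k],
        gene = info[["GENE"]] %||% "", consequence = csq,
        pop_freqs = freqs, pred = preds,
        known_pathogenic = identical(info[["KNOWN_PATH"]], "1"),
        sanger_confirmed = identical(info[["SANGER"]], "1"),
        gt = gts, dp = dps
      )
    }
    rows[[i]] <- bind_rows(site_rows)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- variant_row("1", 1, "A", "C")[0, ]
  }
  validate_variants(out)
  attr(out, "samples") <- samples
  out
}

format_info <- function(v) {
  parts <- character(0)
  if (!is.na(v$gene) && nzchar(v$gene)) parts <- c(parts, paste0("GENE=", v$gene))
  parts <- c(parts, paste0("CSQCLASS=", v$consequence))
  freqs <- v$pop_freqs[[1]]
  for (db in intersect(freq_databases(), names(freqs))) {
    # frequencies serialize to six decimals (the round-trip contract);
    # canonical database order keeps re-serialization byte-stable
    parts <- c(parts, paste0("AF_", db, "=", sprintf("%.6f", freqs[[db]])))
  }
  preds <- v$pred[[1]]
  for (alg in intersect(prediction_algorithms(), names(preds))) {
    parts <- c(parts, paste0("PRED_", alg, "=", pred_to_code[[preds[[alg]]]]))
  }
  parts <- c(parts,
             paste0("KNOWN_PATH=", as.integer(v$known_pathogenic)),
             paste0("SANGER=", as.integer(v$sanger_confirmed)))
  paste(parts, collapse = ";")
}

gt_to_vcf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               hemi = "1", no_call = "./.")

#' Write a variant table as a biallelic VCF v4.2
#'
#' Records are written one per row (already decomposed); an optional
#' `filter` column supplies per-record FILTER tags (used to export removed
#' variants annotated with the cascade stage that removed them).
#'
#' @param variants variant table.
#' @param path output path.
#' @param samples sample column order; defaults to the union of genotyped
#'   sample names in order of first appearance.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL) {
  if (is.null(samples)) {
    samples <- attr(variants, "samples") %||%
      unique(unlist(map(variants$gt, names)))
  }
  filters <- unique(setdiff(variants[["filter"]] %||% character(0), "PASS"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=wesdx",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQCLASS,Number=A,Type=String,Description="Consequence class">',
    vapply(freq_databases(), function(db) sprintf(
      '##INFO=<ID=AF_%s,Number=A,Type=Float,Description="Allele frequency in %s">',
      db, db), ""),
    vapply(prediction_algorithms(), function(alg) sprintf(
      '##INFO=<ID=PRED_%s,Number=1,Type=Character,Description="%s verdict (D/T/U)">',
      alg, alg), ""),
    '##INFO=<ID=KNOWN_PATH,Number=1,Type=Integer,Description="Reported pathogenic (0/1)">',
    '##INFO=<ID=SANGER,Number=1,Type=Integer,Description="Sanger confirmed (0/1)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    vapply(filters, function(f) sprintf(
      '##FILTER=<ID=%s,Description="Removed by cascade stage %s">', f, f), ""),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    gts <- v$gt[[1]]
    dps <- v$dp[[1]]
    cells <- vapply(samples, function(s) {
      g <- if (s %in% names(gts)) gt_to_vcf[[gts[[s]]]] else "./."
      d <- if (s %in% names(dps) && !is.na(dps[[s]])) as.character(as.integer(dps[[s]])) else "."
      paste0(g, ":", d)
    }, "")
    flt <- if (!is.null(variants[["filter"]])) v[["filter"]] else "PASS"
    body[i] <- paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", flt,
                       format_info(v), "GT:DP", cells), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
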