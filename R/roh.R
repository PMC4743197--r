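#' Runs of homozygosity and sib-pair shared haplotypes
#'
#' All four detectors are maximal-run scans over ordered biallelic
#' SNP-array genotype tracks, differing only in the per-SNP predicate:
#'
#' * `single_roh` — the SNP is homozygous (`AA` or `BB`); a heterozygous
#'   call terminates a run.
#' * `sibs_shared_hom` — both siblings homozygous for the *same* allele.
#' * `recessive_shared` — both siblings have the identical genotype
#'   (`AB`/`AB` allowed): the same combination of alleles.
#' * `dominant_shared` — the siblings share at least one allele at the SNP
#'   (only an `AA` vs `BB` conflict breaks a run).
#'
#' `no_call` genotypes are tolerated: they neither break nor support a run,
#' up to a configurable maximum fraction per run. Reported intervals span
#' the outermost supporting SNPs (1-based inclusive, no extrapolation into
#' the flanking gaps) and must satisfy both a minimum supporting-SNP count
#' and a minimum physical length. The predicates are nested (shared-hom
#' implies identical-genotype implies shares-an-allele), so detected
#' intervals nest the same way.
#'
#' @name roh-sharing
NULL

#' Detection minima
#'
#' @param min_snps minimum supporting SNPs per interval (default 25).
#' @param min_length minimum interval length in bp (default 1 Mb).
#' @param max_nocall_frac maximum tolerated fraction of `no_call` genotypes
#'   among the SNPs spanned by a run (default 0.1).
#' @return a `roh_minima` list.
#' @export
roh_minima <- function(min_snps = 25, min_length = 1e6, max_nocall_frac = 0.1) {
  list(min_snps = min_snps, min_length = min_length,
       max_nocall_frac = max_nocall_frac)
}

# maximal-run scan over a per-SNP status vector:
# TRUE = supports, FALSE = breaks, NA = tolerated no-call
scan_runs <- function(pos, status, minima, mode, chrom) {
  breaks <- c(0L, which(!is.na(status) & !status), length(status) + 1L)
  out <- list()
  for (s in seq_len(length(breaks) - 1L)) {
    lo <- breaks[s] + 1L
    hi <- breaks[s + 1L] - 1L
    if (lo > hi) next
    support <- which(!is.na(status[lo:hi]) & status[lo:hi]) + lo - 1L
    if (length(support) == 0) next
    first <- support[1]
    last <- support[length(support)]
    span <- status[first:last]
    n_sup <- sum(!is.na(span) & span)
    n_na <- sum(is.na(span))
    if (n_na / (n_sup + n_na) > minima$max_nocall_frac) next
    len <- pos[last] - pos[first] + 1L
    if (n_sup < minima$min_snps || len < minima$min_length) next
    out[[length(out) + 1]] <- tibble(
      chrom = chrom, start = pos[first], end = pos[last],
      n_snps = n_sup, length_bp = len, mode = mode)
  }
  if (length(out) == 0) {
    tibble(chrom = character(), start = integer(), end = integer(),
           n_snps = integer(), length_bp = integer(), mode = character())
  } else bind_rows(out)
}

single_track <- function(track) {
  if (length(unique(track$sample)) > 1) {
    abort("expected a single-sample track")
  }
  validate_snp_track(track)
}

status_homozygous <- function(g) {
  ifelse(g == "no_call", NA, g %in% c("AA", "BB"))
}

#' @rdname roh-sharing
#' @param track single-sample SNP track tibble (`sample`, `chrom`, `pos`,
#'   `genotype`), sorted by position within chromosome.
#' @param minima a [roh_minima()] list.
#' @return tibble of intervals: `chrom`, `start`, `end`, `n_snps`,
#'   `length_bp`, `mode`.
#' @export
detect_roh_single <- function(track, minima = roh_minima()) {
  track <- single_track(track)
  bind_rows(map(split(track, track$chrom), function(tr) {
    scan_runs(tr$pos, status_homozygous(tr$genotype), minima,
              "single_roh", tr$chrom[1])
  }))
}

align_pair <- function(track_a, track_b) {
  track_a <- single_track(track_a)
  track_b <- single_track(track_b)
  if (nrow(track_a) != nrow(track_b) ||
      !all(track_a$chrom == track_b$chrom) ||
      !all(track_a$pos == track_b$pos)) {
    abort("sib-pair tracks must cover identical SNP positions")
  }
  list(a = track_a, b = track_b)
}

pair_status <- function(ga, gb, predicate) {
  ifelse(ga == "no_call" | gb == "no_call", NA, predicate(ga, gb))
}

scan_pair <- function(track_a, track_b, minima, mode, predicate) {
  tr <- align_pair(track_a, track_b)
  key <- tr$a$chrom
  bind_rows(map(unique(key), function(chr) {
    idx <- key == chr
    scan_runs(tr$a$pos[idx],
              pair_status(tr$a$genotype[idx], tr$b$genotype[idx], predicate),
              minima, mode, chr)
  }))
}

#' @rdname roh-sharing
#' @param track_a,track_b single-sample tracks on identical SNP positions.
#' @export
shared_homozygous_sibs <- function(track_a, track_b, minima = roh_minima()) {
  scan_pair(track_a, track_b, minima, "sibs_shared_hom",
            function(a, b) a == b & a %in% c("AA", "BB"))
}

#' @rdname roh-sharing
#' @export
shared_haplotype_recessive <- function(track_a, track_b, minima = roh_minima()) {
  scan_pair(track_a, track_b, minima, "recessive_shared",
            function(a, b) a == b)
}

#' @rdname roh-sharing
#' @export
shared_haplotype_dominant <- function(track_a, track_b, minima = roh_minima()) {
  scan_pair(track_a, track_b, minima, "dominant_shared",
            function(a, b) !((a == "AA" & b == "BB") | (a == "BB" & b == "AA")))
}

#' Write intervals as BED (0-based half-open) and companion TSV
#'
#' @param intervals interval tibble from the detectors (1-based inclusive).
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the interval tibble.
#' @export
write_intervals <- function(intervals, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end,
                      intervals$mode)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(intervals, tsv_path, progress = FALSE)
  }
  invisible(intervals)
}
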