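#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble tribble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stats rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

#' Round half away from zero
#'
#' Commercial rounding used for all percentages and summary statistics in
#' cohort reports, so that 28.57 % reports as 29 % and -4.45 as -4.5 (base
#' [round()] rounds half to even, which would differ at exact halves).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Canonical variant key
#'
#' Variants are identified throughout the pipeline by the string
#' `chrom:pos:ref:alt`; this is the join key for control-sample lookups,
#' known-pathogenic lookups and relative (Sanger) genotypes.
#'
#' @param chrom,pos,ref,alt vectors of equal length (or a variant table via
#'   the data-frame method below).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  if (is.data.frame(chrom)) {
    v <- chrom
    return(paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

# chromosome label helpers; "23" is the numeric alias some array exports use
is_chrx <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "23")
}

is_autosome <- function(chrom) {
  suppressWarnings(!is.na(as.integer(sub("^chr", "", chrom)))) &
    !(sub("^chr", "", chrom) %in% "23")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
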