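# brute-force oracles, written as direct transliterations of the model and
# run definitions; deliberately plain loops, independent of the package's
# vectorized implementations

o_gt <- function(gt_map, id) {
  if (!id %in% names(gt_map)) return(NA_character_)
  g <- gt_map[[id]]
  if (g == "no_call") NA_character_ else g
}
o_genotyped <- function(gt_map, id) !is.na(o_gt(gt_map, id))
o_carrier <- function(g) !is.na(g) && g %in% c("het", "hom_alt", "hemi")

o_autosome <- function(chrom) grepl("^(chr)?[0-9]+$", chrom) &&
  !sub("chr", "", chrom) %in% "23"
o_is_x <- function(chrom) sub("chr", "", chrom) %in% c("X", "23")

oracle_candidates <- function(variants, ped) {
  fam <- ped$family_id[1]
  aff <- ped$individual_id[ped$affected]
  unaff <- ped$individual_id[!ped$affected]
  sex <- stats::setNames(ped$sex, ped$individual_id)
  fa <- stats::setNames(ped$father_id, ped$individual_id)
  mo <- stats::setNames(ped$mother_id, ped$individual_id)
  parents <- unique(stats::na.omit(c(fa[aff], mo[aff])))
  out <- character(0)
  key <- function(i) wesdx::variant_key(variants[i, ])

  aff_all_in <- function(gt, allowed) {
    gen <- Filter(function(id) o_genotyped(gt, id), aff)
    length(gen) > 0 && all(vapply(gen, function(id) o_gt(gt, id) %in% allowed, TRUE))
  }

  for (i in seq_len(nrow(variants))) {
    gt <- variants$gt[[i]]
    chrom <- variants$chrom[i]
    # AR_hom
    if (o_autosome(chrom) && aff_all_in(gt, "hom_alt")) {
      ok <- TRUE
      for (p in parents) if (o_genotyped(gt, p) && o_gt(gt, p) != "het") ok <- FALSE
      for (u in unaff) if (o_genotyped(gt, u) && o_gt(gt, u) == "hom_alt") ok <- FALSE
      if (ok) out <- c(out, paste("AR_hom", key(i)))
    }
    # AD
    if (o_autosome(chrom) && aff_all_in(gt, c("het", "hom_alt"))) {
      ok <- TRUE
      for (u in unaff) {
        if (o_genotyped(gt, u) && o_carrier(o_gt(gt, u))) ok <- FALSE
      }
      if (ok) out <- c(out, paste("AD", key(i)))
    }
    # XL
    if (o_is_x(chrom)) {
      gen <- Filter(function(id) o_genotyped(gt, id), aff)
      ok <- length(gen) > 0
      for (id in gen) {
        g <- o_gt(gt, id)
        if (sex[[id]] == "male" && g != "hemi") ok <- FALSE
        if (sex[[id]] == "female" && !g %in% c("het", "hom_alt")) ok <- FALSE
      }
      for (u in unaff) {
        if (sex[[u]] == "male" && o_genotyped(gt, u) &&
            o_gt(gt, u) %in% c("hemi", "hom_alt")) ok <- FALSE
      }
      if (ok) out <- c(out, paste("XL", key(i)))
    }
  }
  # AR_comphet over every pair in every gene
  for (g in unique(variants$gene[nzchar(variants$gene)])) {
    idx <- which(variants$gene == g & vapply(variants$chrom, o_autosome, TRUE))
    if (length(idx) < 2) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      gta <- variants$gt[[a]]; gtb <- variants$gt[[b]]
      if (!aff_all_in(gta, "het") || !aff_all_in(gtb, "het")) next
      rejected <- FALSE
      for (child in aff) {
        pf <- fa[[child]]; pm <- mo[[child]]
        if (is.na(pf) || is.na(pm)) next
        if (o_genotyped(gta, pf) && o_genotyped(gta, pm) &&
            o_genotyped(gtb, pf) && o_genotyped(gtb, pm)) {
          fa_a <- o_carrier(o_gt(gta, pf)); mo_a <- o_carrier(o_gt(gta, pm))
          fa_b <- o_carrier(o_gt(gtb, pf)); mo_b <- o_carrier(o_gt(gtb, pm))
          trans <- (fa_a && !mo_a && mo_b && !fa_b) ||
            (mo_a && !fa_a && fa_b && !mo_b)
          if (!trans) rejected <- TRUE
          break
        }
      }
      if (!rejected) {
        out <- c(out, paste("AR_comphet",
                            paste(sort(c(key(a), key(b))), collapse = "+")))
      }
    }
  }
  sort(out)
}

# O(n^2) maximal-interval oracle over a per-SNP status vector
oracle_intervals <- function(pos, status, minima) {
  n <- length(status)
  res <- list()
  blocked <- function(i, j) {
    if (i > j) return(FALSE)
    any(!is.na(status[i:j]) & !status[i:j])
  }
  for (i in seq_len(n)) {
    if (is.na(status[i]) || !status[i]) next
    for (j in i:n) {
      if (is.na(status[j]) || !status[j]) next
      if (blocked(i, j)) break
      # maximality: no supporting SNP reachable left of i or right of j
      left_ext <- FALSE
      for (k in seq_len(i - 1)) {
        if (!is.na(status[k]) && status[k] && !blocked(k, i)) left_ext <- TRUE
      }
      right_ext <- FALSE
      if (j < n) for (k in (j + 1):n) {
        if (!is.na(status[k]) && status[k] && !blocked(j, k)) right_ext <- TRUE
      }
      if (left_ext || right_ext) next
      span <- status[i:j]
      n_sup <- sum(!is.na(span) & span)
      n_na <- sum(is.na(span))
      if (n_na / (n_sup + n_na) > minima$max_nocall_frac) next
      len <- pos[j] - pos[i] + 1
      if (n_sup < minima$min_snps || len < minima$min_length) next
      res[[length(res) + 1]] <- c(pos[i], pos[j], n_sup)
    }
  }
  unique(res)
}

interval_set <- function(intervals) {
  if (nrow(intervals) == 0) return(character(0))
  sort(sprintf("%d-%d-%d", intervals$start, intervals$end, intervals$n_snps))
}

oracle_interval_set <- function(oracle_out) {
  sort(vapply(oracle_out, function(x) sprintf("%d-%d-%d", x[1], x[2], x[3]), ""))
}

random_track <- function(seed, n = NULL, sample_id = "s") {
  set.seed(seed)
  if (is.null(n)) n <- sample(20:200, 1)
  tibble::tibble(
    sample = sample_id, chrom = "1",
    pos = sort(sample.int(5e6, n)),
    genotype = sample(c("AA", "AB", "BB", "no_call"), n, replace = TRUE,
                      prob = c(0.4, 0.3, 0.25, 0.05)))
}

status_of <- function(track, mode, other = NULL) {
  g <- track$genotype
  if (mode == "single") {
    ifelse(g == "no_call", NA, g %in% c("AA", "BB"))
  } else {
    h <- other$genotype
    base <- switch(mode,
      hom = g == h & g %in% c("AA", "BB"),
      combination = g == h,
      one_allele = !((g == "AA" & h == "BB") | (g == "BB" & h == "AA")))
    ifelse(g == "no_call" | h == "no_call", NA, base)
  }
}
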