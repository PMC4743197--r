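# small pedigree / variant builders used across the suite

ped_row <- function(family_id, individual_id, father_id = NA, mother_id = NA,
                    sex = "female", affected = FALSE, consang = FALSE) {
  tibble::tibble(family_id = family_id, individual_id = individual_id,
                 father_id = father_id, mother_id = mother_id, sex = sex,
                 affected = affected, consanguineous_parents = consang)
}

trio_ped <- function(family_id = "FAM", child = "c", child_sex = "female",
                     consang = FALSE) {
  dplyr::bind_rows(
    ped_row(family_id, child, "f", "m", child_sex, affected = TRUE,
            consang = consang),
    ped_row(family_id, "f", sex = "male"),
    ped_row(family_id, "m", sex = "female"))
}

sibpair_ped <- function(family_id = "FAM", with_parents = TRUE) {
  rows <- dplyr::bind_rows(
    ped_row(family_id, "s1", if (with_parents) "f" else NA,
            if (with_parents) "m" else NA, "female", affected = TRUE),
    ped_row(family_id, "s2", if (with_parents) "f" else NA,
            if (with_parents) "m" else NA, "male", affected = TRUE))
  if (with_parents) {
    rows <- dplyr::bind_rows(rows,
                             ped_row(family_id, "f", sex = "male"),
                             ped_row(family_id, "m", sex = "female"))
  }
  rows
}

mk_var <- function(chrom = "1", pos = 1000, ref = "A", alt = "G",
                   gene = "GENE1", consequence = "missense",
                   gt = c(c = "het"), dp = NULL, pop_freqs = numeric(),
                   pred = character(), known_pathogenic = FALSE,
                   sanger_confirmed = FALSE) {
  if (is.null(dp)) dp <- stats::setNames(rep(50, length(gt)), names(gt))
  wesdx::variant_row(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     gene = gene, consequence = consequence,
                     pop_freqs = pop_freqs, pred = pred,
                     known_pathogenic = known_pathogenic,
                     sanger_confirmed = sanger_confirmed, gt = gt, dp = dp)
}

preds_deleterious <- function(k) {
  algs <- c("SIFT", "PolyPhen2", "MutationTaster", "AlignGVGD")
  stats::setNames(c(rep("deleterious", k), rep("tolerated", 4 - k)), algs)
}

# random family generator for property-style model tests
random_family <- function(seed, max_variants = 20) {
  set.seed(seed)
  kind <- sample(c("trio", "quad", "sibpair", "singleton"), 1)
  fam <- "FAM"
  ped <- switch(kind,
    trio = trio_ped(fam, child_sex = sample(c("male", "female"), 1)),
    quad = dplyr::bind_rows(
      trio_ped(fam, child_sex = sample(c("male", "female"), 1)),
      ped_row(fam, "u", "f", "m", sample(c("male", "female"), 1))),
    sibpair = sibpair_ped(fam, with_parents = sample(c(TRUE, FALSE), 1)),
    singleton = ped_row(fam, "c", sex = sample(c("male", "female"), 1),
                        affected = TRUE))
  genotyped <- if (kind == "trio") c("c", sample(c("f", "m"), sample(0:2, 1)))
    else if (kind == "quad") c("c", sample(c("f", "m", "u"), sample(0:3, 1)))
    else if (kind == "sibpair") intersect(c("s1", "s2", "f", "m"),
                                          ped$individual_id)
    else "c"
  genotyped <- unique(genotyped)
  sex_of <- stats::setNames(ped$sex, ped$individual_id)
  n <- sample(1:max_variants, 1)
  vars <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    chrom <- sample(c("1", "2", "3", "X"), 1, prob = c(0.3, 0.3, 0.2, 0.2))
    gts <- vapply(genotyped, function(id) {
      if (chrom == "X" && sex_of[[id]] == "male") {
        sample(c("hom_ref", "hemi", "no_call"), 1, prob = c(0.4, 0.5, 0.1))
      } else {
        sample(c("hom_ref", "het", "hom_alt", "no_call"), 1,
               prob = c(0.25, 0.4, 0.25, 0.1))
      }
    }, "")
    mk_var(chrom = chrom, pos = 1000 * i, gene = sample(c("G1", "G2", "G3"), 1),
           gt = gts)
  }))
  list(ped = ped, variants = vars)
}

random_variants <- function(seed, n = 40) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    freqs <- if (runif(1) < 0.3) numeric() else
      stats::setNames(runif(2, 0, 0.4), sample(c("dbSNP", "1000G", "Seattle",
                                                 "GoNL"), 2))
    mk_var(pos = i * 10, gene = sample(c("GENE1", "OTHER"), 1),
           gt = c(c = sample(c("het", "hom_alt", "hom_ref"), 1)),
           dp = c(c = sample(0:80, 1)), pop_freqs = freqs)
  }))
}

cand_set <- function(candidates) {
  if (nrow(candidates) == 0) return(character(0))
  sort(paste(candidates$model,
             vapply(candidates$keys, function(k) paste(sort(k), collapse = "+"), "")))
}
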