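test_that("homozygous recessive candidates require hom child and het parents", {
  ped <- trio_ped()
  v <- mk_var(gt = c(c = "hom_alt", f = "het", m = "het"),
              dp = c(c = 40, f = 40, m = 40))
  cand <- candidates_recessive(v, ped)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$model, "AR_hom")

  # a homozygous-reference parent is incompatible with transmission
  v2 <- mk_var(gt = c(c = "hom_alt", f = "hom_ref", m = "het"))
  expect_equal(nrow(candidates_recessive(v2, ped)), 0)

  # ungenotyped parents leave the candidate standing
  v3 <- mk_var(gt = c(c = "hom_alt"))
  expect_equal(nrow(candidates_recessive(v3, ped)), 1)

  # an unaffected homozygous sib excludes it
  ped4 <- dplyr::bind_rows(trio_ped(), ped_row("FAM", "u", "f", "m", "male"))
  v4 <- mk_var(gt = c(c = "hom_alt", u = "hom_alt"))
  expect_equal(nrow(candidates_recessive(v4, ped4)), 0)
})

test_that("compound heterozygotes require trans configuration when parents are typed", {
  ped <- sibpair_ped()
  pair <- function(fa1, mo1, fa2, mo2) dplyr::bind_rows(
    mk_var(pos = 100, gene = "G1",
           gt = c(s1 = "het", s2 = "het", f = fa1, m = mo1)),
    mk_var(pos = 200, gene = "G1",
           gt = c(s1 = "het", s2 = "het", f = fa2, m = mo2)))

  trans <- candidates_recessive(pair("het", "hom_ref", "hom_ref", "het"), ped)
  expect_equal(nrow(trans[trans$model == "AR_comphet", ]), 1)
  expect_true(trans$phase_known[trans$model == "AR_comphet"])

  # both alleles from the mother: cis, rejected
  cis <- candidates_recessive(pair("hom_ref", "het", "hom_ref", "het"), ped)
  expect_equal(nrow(cis[cis$model == "AR_comphet", ]), 0)

  # parents unavailable: pair kept, flagged phase-unknown
  ped2 <- sibpair_ped(with_parents = FALSE)
  v2 <- dplyr::bind_rows(
    mk_var(pos = 100, gene = "G1", gt = c(s1 = "het", s2 = "het")),
    mk_var(pos = 200, gene = "G1", gt = c(s1 = "het", s2 = "het")))
  ph <- candidates_recessive(v2, ped2)
  ph <- ph[ph$model == "AR_comphet", ]
  expect_equal(nrow(ph), 1)
  expect_false(ph$phase_known)

  # different genes never pair
  v3 <- dplyr::bind_rows(
    mk_var(pos = 100, gene = "G1", gt = c(s1 = "het", s2 = "het")),
    mk_var(pos = 200, gene = "G2", gt = c(s1 = "het", s2 = "het")))
  expect_equal(nrow(candidates_recessive(v3, ped2) |>
                      dplyr::filter(model == "AR_comphet")), 0)
})

test_that("dominant candidates track transmission and de novo status", {
  # inherited from an affected mother; unaffected aunt non-carrier
  ped <- dplyr::bind_rows(
    ped_row("FAM", "c", "f", "m", "male", affected = TRUE),
    ped_row("FAM", "f", sex = "male"),
    ped_row("FAM", "m", sex = "female", affected = TRUE),
    ped_row("FAM", "aunt", sex = "female"))
  v <- mk_var(gt = c(c = "het", m = "het", aunt = "hom_ref"))
  cand <- candidates_dominant(v, ped)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$de_novo_status, "inherited")

  # carrier unaffected aunt is a segregation violation
  v2 <- mk_var(gt = c(c = "het", m = "het", aunt = "het"))
  expect_equal(nrow(candidates_dominant(v2, ped)), 0)

  # de novo: both parents genotyped negative
  trio <- trio_ped()
  v3 <- mk_var(gt = c(c = "het", f = "hom_ref", m = "hom_ref"))
  expect_identical(candidates_dominant(v3, trio)$de_novo_status, "confirmed")

  # only the mother tested negative: probable
  v4 <- mk_var(gt = c(c = "het", m = "hom_ref"))
  expect_identical(candidates_dominant(v4, trio)$de_novo_status, "probable")

  # nobody tested: unknown
  v5 <- mk_var(gt = c(c = "het"))
  expect_identical(candidates_dominant(v5, trio)$de_novo_status, "unknown")

  # homozygous-ALT affected is allowed but flagged for down-ranking
  v6 <- mk_var(gt = c(c = "hom_alt"))
  c6 <- candidates_dominant(v6, trio)
  expect_true(c6$hom_alt_ad)
})

test_that("X-linked candidates respect sex-specific genotype rules", {
  trio <- trio_ped(child_sex = "female")
  v <- mk_var(chrom = "X", gt = c(c = "het", f = "hom_ref", m = "hom_ref"))
  cand <- candidates_xlinked(v, trio)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$de_novo_status, "confirmed")

  # an unaffected hemizygous brother excludes the allele
  ped2 <- dplyr::bind_rows(trio, ped_row("FAM", "b", "f", "m", "male"))
  v2 <- mk_var(chrom = "X", gt = c(c = "het", b = "hemi"))
  expect_equal(nrow(candidates_xlinked(v2, ped2)), 0)

  # autosomal variants are never X-linked candidates
  v3 <- mk_var(chrom = "7", gt = c(c = "het"))
  expect_equal(nrow(candidates_xlinked(v3, trio)), 0)

  # affected hemizygous male qualifies
  triom <- trio_ped(child_sex = "male")
  v4 <- mk_var(chrom = "X", gt = c(c = "hemi", m = "het"))
  expect_equal(nrow(candidates_xlinked(v4, triom)), 1)
})

test_that("sequential ordering lists recessive candidates first", {
  ped <- trio_ped()
  v <- dplyr::bind_rows(
    mk_var(pos = 100, gene = "GA", gt = c(c = "het", f = "hom_ref", m = "hom_ref")),
    mk_var(pos = 200, gene = "GB", gt = c(c = "hom_alt", f = "het", m = "het")))
  cand <- apply_sequential_models(v, ped)
  expect_identical(cand$model[1], "AR_hom")
  expect_true(all(diff(cand$priority) >= 0))

  # no candidates: family stays empty, not an error
  v0 <- mk_var(gt = c(c = "hom_ref", f = "het", m = "het"))
  expect_equal(nrow(apply_sequential_models(v0, ped)), 0)
})

test_that("model candidates match brute-force enumeration on random families", {
  for (seed in 1:200) {
    fam <- random_family(seed)
    got <- cand_set(apply_sequential_models(fam$variants, fam$ped))
    want <- oracle_candidates(fam$variants, fam$ped)
    expect_identical(got, want, label = paste("seed", seed))
  }
})

test_that("reported compound-het pairs are trans whenever parents are genotyped", {
  found <- 0
  for (seed in 1:200) {
    fam <- random_family(seed)
    cand <- candidates_recessive(fam$variants, fam$ped)
    cand <- cand[cand$model == "AR_comphet" & cand$phase_known %in% TRUE, ]
    for (i in seq_len(nrow(cand))) {
      vs <- cand$variants[[i]]
      fa_carries <- vapply(1:2, function(j) {
        g <- vs$gt[[j]]["f"]; !is.na(g) && g %in% c("het", "hom_alt")
      }, TRUE)
      mo_carries <- vapply(1:2, function(j) {
        g <- vs$gt[[j]]["m"]; !is.na(g) && g %in% c("het", "hom_alt")
      }, TRUE)
      expect_identical(sort(paste(fa_carries, mo_carries)),
                       c("FALSE TRUE", "TRUE FALSE"))
      found <- found + 1
    }
  }
  expect_gt(found, 0)
})

test_that("adding an unrelated variant never removes a candidate", {
  for (seed in 201:220) {
    fam <- random_family(seed)
    before <- cand_set(apply_sequential_models(fam$variants, fam$ped))
    genotyped <- names(fam$variants$gt[[1]])
    extra <- mk_var(chrom = "2", pos = 999999, gene = "UNRELATED",
                    gt = stats::setNames(rep("het", length(genotyped)), genotyped))
    after <- cand_set(apply_sequential_models(
      dplyr::bind_rows(fam$variants, extra), fam$ped))
    expect_true(all(before %in% after), label = paste("seed", seed))
  }
})
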