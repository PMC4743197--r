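panel1 <- tibble::tibble(
  gene = c("GENE1", "GENEAD"),
  hpo_terms = list(c("HP:0000252", "HP:0011451"), c("HP:0000252")),
  disorder = c("Disorder A", "Disorder B"),
  inheritance_modes = list("AR", "AD"))

cand_of <- function(v, ped, model = NULL) {
  cand <- apply_sequential_models(v, ped)
  if (!is.null(model)) cand <- cand[cand$model == model, ]
  cand
}

test_that("evidence classes follow the stated priority", {
  ped <- trio_ped()
  # truncating variant in a matching panel gene, unobserved in databases
  v <- mk_var(gene = "GENE1", consequence = "frameshift",
              gt = c(c = "hom_alt", f = "het", m = "het"),
              sanger_confirmed = TRUE)
  cand <- cand_of(v, ped, "AR_hom")
  ev <- assess_evidence(cand, panel1, "HP:0000252")
  expect_identical(ev$deleteriousness, "truncating_or_splice")
  expect_true(ev$gene_disease_match)
  expect_true(ev$population_absent)
  expect_true(ev$deleterious_sufficient)

  # missense with three deleterious verdicts
  v2 <- mk_var(gene = "GENE1", consequence = "missense",
               pred = preds_deleterious(3),
               gt = c(c = "hom_alt", f = "het", m = "het"))
  ev2 <- assess_evidence(cand_of(v2, ped, "AR_hom"), panel1, "HP:0000252")
  expect_identical(ev2$deleteriousness, "predicted_deleterious_3")
  expect_true(ev2$deleterious_sufficient)

  # two verdicts are insufficient
  v3 <- mk_var(gene = "GENE1", consequence = "missense",
               pred = preds_deleterious(2),
               gt = c(c = "hom_alt", f = "het", m = "het"))
  ev3 <- assess_evidence(cand_of(v3, ped, "AR_hom"), panel1, "HP:0000252")
  expect_false(ev3$deleterious_sufficient)

  # known pathogenic beats consequence class; 0.13 % stays population-absent
  v4 <- mk_var(gene = "GENE1", consequence = "missense",
               known_pathogenic = TRUE, pop_freqs = c(ExAC = 0.0013),
               gt = c(c = "hom_alt", f = "het", m = "het"))
  ev4 <- assess_evidence(cand_of(v4, ped, "AR_hom"), panel1, "HP:0000252")
  expect_identical(ev4$deleteriousness, "known_pathogenic")
  expect_true(ev4$population_absent)

  # a frequency above the ceiling breaks population absence
  v5 <- mk_var(gene = "GENE1", pop_freqs = c(EVS = 0.05),
               gt = c(c = "hom_alt", f = "het", m = "het"))
  ev5 <- assess_evidence(cand_of(v5, ped, "AR_hom"), panel1, "HP:0000252")
  expect_false(ev5$population_absent)

  # panel inheritance mode must include the candidate's model
  vad <- mk_var(gene = "GENE1", gt = c(c = "het", f = "hom_ref", m = "hom_ref"))
  evad <- assess_evidence(cand_of(vad, ped, "AD"), panel1, "HP:0000252")
  expect_false(evad$gene_disease_match)

  # gene absent from the panel: no match, not an error
  voff <- mk_var(gene = "ELSEWHERE",
                 gt = c(c = "hom_alt", f = "het", m = "het"))
  expect_false(assess_evidence(cand_of(voff, ped, "AR_hom"), panel1,
                               "HP:0000252")$gene_disease_match)
})

test_that("compound-het evidence requires both alleles to qualify", {
  ped <- sibpair_ped(with_parents = FALSE)
  v <- dplyr::bind_rows(
    mk_var(pos = 100, gene = "GENE1", consequence = "frameshift",
           gt = c(s1 = "het", s2 = "het"), sanger_confirmed = TRUE),
    mk_var(pos = 200, gene = "GENE1", consequence = "missense",
           pred = preds_deleterious(2),
           gt = c(s1 = "het", s2 = "het"), sanger_confirmed = TRUE))
  cand <- cand_of(v, ped, "AR_comphet")
  ev <- assess_evidence(cand, panel1, "HP:0000252")
  expect_false(ev$deleterious_sufficient)  # weaker allele only has k = 2
  expect_identical(ev$deleteriousness, "predicted_deleterious_2")
})

test_that("segregation verdicts cover yes, no and untestable", {
  ped <- trio_ped()
  v <- mk_var(gene = "GENE1", gt = c(c = "hom_alt", f = "het", m = "het"))
  cand <- cand_of(v, ped, "AR_hom")
  expect_identical(check_segregation(cand[1, ], ped), "yes")

  # AD variant carried by an unaffected genotyped relative
  pedA <- dplyr::bind_rows(trio_ped(), ped_row("FAM", "aunt", sex = "female"))
  vA <- mk_var(gene = "GENEAD", gt = c(c = "het"))
  candA <- cand_of(vA, pedA, "AD")
  vA2 <- vA
  vA2$gt <- list(c(c = "het", aunt = "het"))
  candA$variants <- list(vA2)
  expect_identical(check_segregation(candA[1, ], pedA), "no")

  # singleton: nothing to test
  peds <- ped_row("FAM", "c", sex = "female", affected = TRUE)
  vs <- mk_var(gt = c(c = "het"))
  cands <- cand_of(vs, peds, "AD")
  expect_identical(check_segregation(cands[1, ], peds), "untestable")
})

test_that("verdicts follow the causality rule and its boundaries", {
  ped <- trio_ped()
  v <- mk_var(gene = "GENE1", consequence = "frameshift",
              gt = c(c = "hom_alt", f = "het", m = "het"),
              sanger_confirmed = TRUE)
  cand <- cand_of(v, ped, "AR_hom")
  ev <- assess_evidence(cand, panel1, "HP:0000252")
  out <- classify(cand, ev, "yes")
  expect_identical(out$verdict, "causative")

  # without Sanger confirmation, never causative
  v2 <- v; v2$sanger_confirmed <- FALSE
  cand2 <- cand_of(v2, ped, "AR_hom")
  out2 <- classify(cand2, assess_evidence(cand2, panel1, "HP:0000252"), "yes")
  expect_identical(out2$verdict, "candidate")

  # k = 2 predicted, non-truncating: candidate at best
  v3 <- mk_var(gene = "GENE1", consequence = "missense",
               pred = preds_deleterious(2), sanger_confirmed = TRUE,
               gt = c(c = "hom_alt", f = "het", m = "het"))
  cand3 <- cand_of(v3, ped, "AR_hom")
  out3 <- classify(cand3, assess_evidence(cand3, panel1, "HP:0000252"), "yes")
  expect_identical(out3$verdict, "candidate")

  # contradicting segregation excludes regardless of other evidence
  out4 <- classify(cand, ev, "no")
  expect_identical(out4$verdict, "excluded")
})

test_that("the verdict rule is monotone over the whole evidence lattice", {
  seg_levels <- c(no = 0, untestable = 1, yes = 2)
  verdict_levels <- c(excluded = 0, candidate = 1, causative = 2)
  grid <- expand.grid(match = c(FALSE, TRUE), del = c(FALSE, TRUE),
                      pop = c(FALSE, TRUE), seg = names(seg_levels),
                      sanger = c(FALSE, TRUE), stringsAsFactors = FALSE)
  grid$verdict <- vapply(seq_len(nrow(grid)), function(i) {
    verdict_rule(grid$match[i], grid$del[i], grid$pop[i], grid$seg[i],
                 grid$sanger[i])
  }, "")
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      ge <- grid$match[j] >= grid$match[i] && grid$del[j] >= grid$del[i] &&
        grid$pop[j] >= grid$pop[i] &&
        seg_levels[[grid$seg[j]]] >= seg_levels[[grid$seg[i]]] &&
        grid$sanger[j] >= grid$sanger[i]
      if (ge) {
        expect_gte(verdict_levels[[grid$verdict[j]]],
                   verdict_levels[[grid$verdict[i]]])
      }
    }
  }
})

test_that("ranking puts causative recessive candidates first", {
  ped <- trio_ped()
  v <- dplyr::bind_rows(
    mk_var(pos = 100, gene = "GENE1", consequence = "frameshift",
           sanger_confirmed = TRUE,
           gt = c(c = "hom_alt", f = "het", m = "het")),
    mk_var(pos = 200, gene = "GENEAD", consequence = "frameshift",
           sanger_confirmed = TRUE,
           gt = c(c = "het", f = "hom_ref", m = "hom_ref")))
  cand <- apply_sequential_models(v, ped)
  ev <- assess_evidence(cand, panel1, "HP:0000252")
  seg <- vapply(seq_len(nrow(cand)), function(i) {
    check_segregation(cand[i, ], ped)
  }, "")
  out <- classify(cand, ev, seg)
  expect_identical(out$model[out$rank == 1], "AR_hom")
})

test_that("the known-pathogenic fallback recovers unmatched lookup variants", {
  lookup <- tibble::tibble(chrom = "7", pos = 100L, ref = "A", alt = "G",
                           gene = "KP1", disorder = "Lookup disorder")
  v <- dplyr::bind_rows(
    mk_var(chrom = "7", pos = 100, gene = "KP1"),
    mk_var(chrom = "7", pos = 200, gene = "KP2"))
  fb <- hgmd_fallback(v, lookup)
  expect_equal(fb$pos, 100L)
  expect_equal(nrow(hgmd_fallback(v, lookup[0, ])), 0)
  expect_equal(nrow(hgmd_fallback(v[0, ], lookup)), 0)

  # fallback candidates get their phenotype match from the lookup
  ped <- trio_ped()
  vf <- mk_var(chrom = "7", pos = 100, ref = "A", alt = "G", gene = "KP1",
               consequence = "frameshift", sanger_confirmed = TRUE,
               gt = c(c = "het", f = "hom_ref", m = "hom_ref"))
  cand <- cand_of(vf, ped, "AD")
  cand$fallback <- TRUE
  ev <- assess_evidence(cand, panel1, "HP:0000252", known_pathogenic = lookup)
  expect_true(ev$gene_disease_match)
  expect_identical(ev$deleteriousness, "known_pathogenic")
})
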