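two_vars <- function(dp1, dp2) {
  dplyr::bind_rows(
    mk_var(pos = 100, gt = c(c = "het"), dp = c(c = dp1)),
    mk_var(pos = 200, gt = c(c = "het"), dp = c(c = dp2)))
}

test_that("read-depth filter removes depth 4 and keeps depth 5", {
  v <- two_vars(4, 5)
  res <- filter_min_reads(v, affected = "c", min_reads = 5)
  expect_equal(res$removed$pos, 100L)
  expect_equal(res$kept$pos, 200L)

  # min_reads 0 is the identity
  res0 <- filter_min_reads(v, affected = "c", min_reads = 0)
  expect_equal(nrow(res0$removed), 0)

  # missing depth counts as zero (variant removed, with a warning)
  vm <- mk_var(gt = c(c = "het"), dp = c(c = NA_real_))
  expect_warning(resm <- filter_min_reads(vm, "c", 5), "treated as 0")
  expect_equal(nrow(resm$removed), 1)

  # the rule looks at affected carriers only: a low-depth non-carrier
  # genotype does not remove the variant
  vn <- mk_var(gt = c(c = "het", s = "hom_ref"), dp = c(c = 50, s = 1))
  resn <- filter_min_reads(vn, affected = c("c", "s"), min_reads = 5)
  expect_equal(nrow(resn$removed), 0)
})

test_that("population-frequency filter is strict and per consulted database", {
  v <- dplyr::bind_rows(
    mk_var(pos = 1, pop_freqs = c(`1000G` = 0.021)),
    mk_var(pos = 2, pop_freqs = c(`1000G` = 0.020)),
    mk_var(pos = 3, pop_freqs = numeric()),
    mk_var(pos = 4, pop_freqs = c(ExAC = 0.30)))
  res <- filter_population_frequency(v)
  expect_equal(res$removed$pos, 1L)            # 2.1 % > 2 %
  expect_setequal(res$kept$pos, c(2L, 3L, 4L)) # boundary, unobserved,
                                               # and unconsulted database
  # a known-pathogenic allele at ExAC 0.13 % survives
  kp <- mk_var(pop_freqs = c(ExAC = 0.0013), known_pathogenic = TRUE)
  expect_equal(nrow(filter_population_frequency(kp)$removed), 0)

  neg <- mk_var(pop_freqs = c(dbSNP = -0.1))
  expect_error(filter_population_frequency(neg), "negative")
})

test_that("run-control filter thresholds on identical-allele recurrence", {
  v <- mk_var(chrom = "1", pos = 100, ref = "A", alt = "G")
  mk_controls <- function(n) {
    tibble::tibble(sample = sprintf("CTL%02d", seq_len(n)),
                   chrom = "1", pos = 100L, ref = "A", alt = "G")
  }
  expect_equal(nrow(filter_run_controls(v, mk_controls(8), 4)$removed), 1)
  res0 <- filter_run_controls(v, tibble::tibble(
    sample = "CTL01", chrom = "2", pos = 5L, ref = "C", alt = "T"), 4)
  expect_equal(nrow(res0$removed), 0)
  expect_equal(nrow(filter_run_controls(v, mk_controls(4), 4)$removed), 1)
  expect_equal(nrow(filter_run_controls(v, mk_controls(4), 5)$removed), 0)
  expect_warning(res <- filter_run_controls(v, NULL, 4), "skipped")
  expect_equal(nrow(res$kept), 1)
})

panel_of <- function(...) {
  rows <- list(...)
  tibble::tibble(
    gene = vapply(rows, `[[`, "", 1),
    hpo_terms = lapply(rows, function(r) strsplit(r[[2]], ",")[[1]]),
    disorder = "D",
    inheritance_modes = lapply(rows, function(r) c("AR", "AD", "XL")))
}

test_that("phenotype-panel filter routes matched and unmatched", {
  panel <- panel_of(list("GENE1", "HP:0000253"), list("GENE2", "HP:0009999"))
  v <- dplyr::bind_rows(
    mk_var(pos = 1, gene = "GENE1"),
    mk_var(pos = 2, gene = "GENE2"),
    mk_var(pos = 3, gene = ""),
    mk_var(pos = 4, gene = "NOTPANEL"))
  res <- filter_phenotype_panel(v, panel, "HP:0000253")
  expect_equal(res$matched$pos, 1L)
  expect_setequal(res$unmatched$pos, c(2L, 3L, 4L))

  empty <- filter_phenotype_panel(v, panel[0, ], "HP:0000253")
  expect_equal(nrow(empty$matched), 0)
  expect_equal(nrow(empty$unmatched), 4)
})

test_that("ontology closure matching picks up descendant terms", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000252", "",
               "[Term]", "id: HP:0011451", "is_a: HP:0000252 ! microcephaly"),
             obo)
  ont <- read_hpo_ontology(obo)
  panel <- panel_of(list("GENE1", "HP:0011451"))
  v <- mk_var(gene = "GENE1")
  # plain intersection fails: panel term is a child of the query term
  expect_equal(nrow(filter_phenotype_panel(v, panel, "HP:0000252")$matched), 0)
  expect_equal(nrow(filter_phenotype_panel(v, panel, "HP:0000252",
                                           ontology = ont)$matched), 1)
})

test_that("cascade thresholds are monotone and depth/frequency commute", {
  for (seed in 1:5) {
    v <- random_variants(seed)
    # nested surviving sets over an AF grid
    prev <- NULL
    for (af in c(0.005, 0.02, 0.1, 0.3, 1)) {
      kept <- variant_key(filter_population_frequency(v, max_af = af)$kept)
      if (!is.null(prev)) expect_true(all(prev %in% kept))
      prev <- kept
    }
    # lowering min_reads never shrinks the surviving set
    prev <- NULL
    for (mr in c(40, 20, 5, 0)) {
      kept <- variant_key(filter_min_reads(v, "c", mr)$kept)
      if (!is.null(prev)) expect_true(all(prev %in% kept))
      prev <- kept
    }
    # commutativity
    ab <- filter_population_frequency(
      filter_min_reads(v, "c", 5)$kept)$kept
    ba <- filter_min_reads(
      filter_population_frequency(v)$kept, "c", 5)$kept
    expect_identical(variant_key(ab), variant_key(ba))
  }
})

test_that("the full cascade conserves every variant exactly once", {
  panel <- panel_of(list("GENE1", "HP:0000253"))
  cfg <- cascade_config(hpo_query_terms = "HP:0000253")
  for (seed in 6:10) {
    v <- random_variants(seed)
    res <- suppressWarnings(apply_cascade(v, "c", panel, NULL, cfg))
    validate_trace(res$trace)
    all_keys <- sort(c(variant_key(res$matched), variant_key(res$unmatched),
                       variant_key(res$removed)))
    expect_identical(all_keys, sort(variant_key(v)))
    expect_equal(res$trace$n_in[1], nrow(v))
    expect_equal(res$trace$n_out[nrow(res$trace)], nrow(res$matched))
  }
})

test_that("a cascade with disabled thresholds is the identity", {
  v <- random_variants(11)
  panel <- panel_of(list("GENE1", "HP:0000253"), list("OTHER", "HP:0000253"))
  cfg <- cascade_config(min_reads = 0, max_af = 1,
                        hpo_query_terms = "HP:0000253")
  res <- suppressWarnings(apply_cascade(v, "c", panel, NULL, cfg))
  expect_equal(nrow(res$removed), 0)
  expect_identical(sort(variant_key(res$matched)), sort(variant_key(v)))
})

test_that("trace validation catches inconsistent accounting", {
  bad <- tibble::tibble(stage = c("a", "b"), n_in = c(10L, 8L),
                        n_removed = c(1L, 2L), n_out = c(9L, 6L))
  expect_error(validate_trace(bad), "stage k")
  bad2 <- tibble::tibble(stage = "a", n_in = 10L, n_removed = 3L, n_out = 8L)
  expect_error(validate_trace(bad2), "n_out")
})

test_that("cascade config validates and loads from YAML", {
  expect_error(cascade_config(min_reads = -1), "min_reads")
  expect_error(cascade_config(max_af = 1.5), "max_af")
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_reads: 10", "max_af: 0.01",
               "hpo_query_terms:", "  - HP:0000252"), yml)
  cfg <- read_cascade_config(yml)
  expect_equal(cfg$min_reads, 10)
  expect_equal(cfg$max_af, 0.01)
  expect_identical(cfg$hpo_query_terms, "HP:0000252")
  writeLines("bogus_key: 1", yml)
  expect_error(read_cascade_config(yml), "unknown cascade config key")
})
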