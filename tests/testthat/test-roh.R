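mk_track <- function(genotypes, start = 1e6, step = 40e3, sample_id = "s") {
  tibble::tibble(sample = sample_id, chrom = "1",
                 pos = as.integer(start + step * (seq_along(genotypes) - 1)),
                 genotype = genotypes)
}

test_that("single-patient ROH detection finds qualifying homozygous runs", {
  # 30 consecutive homozygous SNPs spanning 1.16 Mb pass 25 SNP / 1 Mb minima
  tr <- mk_track(rep("AA", 30))
  iv <- detect_roh_single(tr)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 1e6)
  expect_equal(iv$end, 1e6 + 29 * 40e3)
  expect_equal(iv$n_snps, 30L)

  # one heterozygous call mid-run splits it into two failing halves
  g <- rep("AA", 30); g[15] <- "AB"
  expect_equal(nrow(detect_roh_single(mk_track(g))), 0)

  # no-calls are tolerated and do not count as support
  g2 <- rep("BB", 32); g2[c(10, 20)] <- "no_call"
  iv2 <- detect_roh_single(mk_track(g2))
  expect_equal(iv2$n_snps, 30L)

  # unsorted input is rejected
  bad <- mk_track(rep("AA", 10))
  bad$pos[2] <- bad$pos[1]
  expect_error(detect_roh_single(bad), "strictly increasing")
})

test_that("sib-pair sharing modes implement their per-SNP predicates", {
  a <- mk_track(rep("AA", 30), sample_id = "a")
  b <- mk_track(rep("AA", 30), sample_id = "b")
  expect_equal(nrow(shared_homozygous_sibs(a, b)), 1)

  # an opposite-homozygote SNP breaks every mode
  b2 <- b; b2$genotype[15] <- "BB"
  expect_equal(nrow(shared_homozygous_sibs(a, b2)), 0)
  expect_equal(nrow(shared_haplotype_dominant(a, b2)), 0)

  # identical heterozygous genotypes support recessive but not hom sharing
  a3 <- mk_track(rep("AB", 30), sample_id = "a")
  b3 <- mk_track(rep("AB", 30), sample_id = "b")
  expect_equal(nrow(shared_homozygous_sibs(a3, b3)), 0)
  expect_equal(nrow(shared_haplotype_recessive(a3, b3)), 1)

  # AA vs AB shares an allele: dominant mode only
  b4 <- mk_track(rep("AB", 30), sample_id = "b")
  expect_equal(nrow(shared_haplotype_recessive(a, b4)), 0)
  expect_equal(nrow(shared_haplotype_dominant(a, b4)), 1)

  # position mismatch is a validation error
  b5 <- b; b5$pos <- b5$pos + 1L
  expect_error(shared_homozygous_sibs(a, b5), "identical SNP positions")
})

test_that("detectors reproduce the brute-force maximal-interval oracle", {
  minima <- roh_minima(min_snps = 3, min_length = 10, max_nocall_frac = 0.25)
  for (seed in 1:100) {
    tr <- random_track(seed)
    got <- detect_roh_single(tr, minima)
    want <- oracle_intervals(tr$pos, status_of(tr, "single"), minima)
    expect_identical(interval_set(got), oracle_interval_set(want),
                     label = paste("single seed", seed))
  }
  for (seed in 101:130) {
    a <- random_track(seed, sample_id = "a")
    b <- random_track(seed + 1000, n = nrow(a), sample_id = "b")
    b$pos <- a$pos
    pairs <- list(
      hom = shared_homozygous_sibs(a, b, minima),
      combination = shared_haplotype_recessive(a, b, minima),
      one_allele = shared_haplotype_dominant(a, b, minima))
    for (mode in names(pairs)) {
      want <- oracle_intervals(a$pos, status_of(a, mode, b), minima)
      expect_identical(interval_set(pairs[[mode]]), oracle_interval_set(want),
                       label = paste(mode, "seed", seed))
    }
  }
})

test_that("sharing modes nest: hom within recessive within dominant", {
  # nesting is a property of the per-SNP predicates; the no-call-fraction
  # cap is a data-quality knob that can reject a looser-mode superinterval,
  # so it is disabled here
  minima <- roh_minima(min_snps = 3, min_length = 10, max_nocall_frac = 1)
  contained_in <- function(inner, outer) {
    all(vapply(seq_len(nrow(inner)), function(i) {
      any(outer$start <= inner$start[i] & outer$end >= inner$end[i])
    }, TRUE))
  }
  for (seed in 301:340) {
    a <- random_track(seed, sample_id = "a")
    b <- random_track(seed + 2000, n = nrow(a), sample_id = "b")
    b$pos <- a$pos
    hom <- shared_homozygous_sibs(a, b, minima)
    rec <- shared_haplotype_recessive(a, b, minima)
    dom <- shared_haplotype_dominant(a, b, minima)
    expect_true(contained_in(hom, rec), label = paste("hom<rec seed", seed))
    expect_true(contained_in(rec, dom), label = paste("rec<dom seed", seed))
  }
})

test_that("a planted 8 Mb homozygous stretch is recovered at array density", {
  set.seed(20)
  roh <- c(21e6, 29e6 - 1)
  tr <- generate_snp_track("5", 1e6, 49e6, density = 40, roh = roh)
  tr$sample <- "p"
  iv <- detect_roh_single(tr)
  top <- iv[which.max(iv$length_bp), ]
  expect_equal(round_half_away(top$length_bp / 1e6), 8)
  overlap <- min(top$end, roh[2]) - max(top$start, roh[1]) + 1
  expect_gte(overlap / (roh[2] - roh[1] + 1), 0.95)
})

test_that("planted sib-pair sharing segments are recovered in their mode", {
  set.seed(21)
  pair <- generate_sib_pair_tracks("9", 20e6, 70e6, density = 40,
                                   shared = c(40e6, 48e6), mode = "combination")
  pair$a$sample <- "a"; pair$b$sample <- "b"
  rec <- shared_haplotype_recessive(pair$a, pair$b)
  top <- rec[which.max(rec$length_bp), ]
  expect_gte(min(top$end, 48e6) - max(top$start, 40e6) + 1, 0.95 * 8e6)
})
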