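#' Synthetic diagnostic-exome cohort generator
#'
#' Generates a complete cohort bundle — pedigrees, phenotype table,
#' per-family annotated variant sets, same-run control samples, Sanger
#' relative genotypes, SNP-array tracks, gene panel and known-pathogenic
#' lookup — with the statistical structure the prioritization pipeline
#' assumes. The default configuration emulates a 35-family intellectual
#' disability / microcephaly cohort (38 patients, three sib-pairs, six
#' consanguineous families) in which ten families carry an established
#' causal genotype ([causal_specs_default()]): seven autosomal recessive
#' (three homozygous, four compound heterozygous), two autosomal dominant
#' and one X-linked de novo. A machine-readable truth ledger records every
#' planted causal variant and homozygosity interval so recovery can be
#' tested end to end.
#'
#' @name synthetic-cohort
NULL

#' The ten default causal configurations
#'
#' One row per diagnosed family: gene, chromosome, inheritance model, the
#' causal allele(s) with consequence class and literature status, and the
#' segregation plan (which relatives were Sanger-genotyped and what they
#' carry). Compound-heterozygous specs carry exactly two alleles with
#' distinct parental origins; homozygous specs one allele carried
#' heterozygously by both parents.
#'
#' @return tibble of causal specifications.
#' @export
causal_specs_default <- function() {
  v <- function(pos, ref, alt, consequence, known = FALSE, preds = 0L,
                exac = NA_real_) {
    tibble(pos = as.integer(pos), ref = ref, alt = alt,
           consequence = consequence, known_pathogenic = known,
           n_deleterious_preds = preds, af_exac = exac)
  }
  tribble(
    ~family_index, ~gene, ~chrom, ~model, ~disorder, ~variants, ~segregation_plan,
    1L, "RAB3GAP1", "2", "AR_hom", "Warburg Micro syndrome 1",
    list(v(135888000, "CACTG", "C", "frameshift", known = TRUE)), "parents",
    4L, "KIF11", "10", "AD", "Microcephaly with or without chorioretinopathy, lymphedema, or mental retardation",
    list(v(94352000, "A", "AT", "frameshift")), "affected_mother_aunt",
    6L, "ASPM", "1", "AR_comphet", "Primary microcephaly 5",
    list(bind_rows(v(197070000, "GAGAA", "G", "frameshift"),
                   v(197075000, "G", "C", "splice_site"))), "parents",
    8L, "RTTN", "18", "AR_comphet", "Polymicrogyria with seizures",
    list(bind_rows(v(67800000, "AC", "A", "frameshift"),
                   v(67840000, "A", "G", "missense", preds = 3L))), "parents_and_sibs",
    16L, "ERCC8", "5", "AR_hom", "Cockayne syndrome type A",
    list(v(60200000, "GCGA", "GTG", "frameshift")), "parents",
    19L, "CASK", "X", "XL", "Mental retardation and microcephaly with pontine and cerebellar hypoplasia",
    list(v(41480000, "T", "G", "splice_site")), "parents_negative",
    23L, "DYRK1A", "21", "AD", "Autosomal dominant mental retardation 7",
    list(v(38858000, "CT", "C", "frameshift")), "mother_negative",
    24L, "BRCA2", "13", "AR_hom", "Fanconi anemia, complementation group D1",
    list(v(32950000, "T", "TA", "frameshift", known = TRUE)), "parents",
    26L, "RNASEH2B", "13", "AR_comphet", "Aicardi-Goutieres syndrome 2",
    list(bind_rows(v(51520000, "G", "A", "missense", known = TRUE, preds = 3L, exac = 0.0013),
                   v(51525000, "T", "G", "missense", preds = 3L))), "parents",
    32L, "ASPM", "1", "AR_comphet", "Primary microcephaly 5",
    list(bind_rows(v(197060000, "C", "T", "stop_gained", known = TRUE),
                   v(197065000, "T", "TA", "frameshift"))), "parents"
  )
}

#' Cohort configuration
#'
#' @param n_families number of families (default 35; must be at least the
#'   number of causal specs).
#' @param seed mandatory RNG seed; the bundle is a deterministic function
#'   of the configuration.
#' @param specs causal specifications (default [causal_specs_default()]).
#' @param n_background annotated background variants per family (default
#'   200).
#' @param prop_common fraction of background variants drawn from the
#'   common-frequency stratum, present in all consulted databases with
#'   allele frequency 5-50 % (default 0.9); the remainder are rare
#'   (absent, or below 2 % in a random subset of databases).
#' @param prop_in_panel fraction of background variants placed in panel
#'   genes (default 0.15), so the phenotype filter passes a realistic
#'   residue.
#' @param low_depth_rate fraction of background variants given read depth
#'   below 5 (default 0.05), exercising the depth filter.
#' @param n_controls number of same-run control samples (default 8).
#' @param n_artifacts recurrent artifact alleles present in every patient
#'   and every control sample (default 8).
#' @param n_panel_decoys additional panel genes unrelated to the planted
#'   diagnoses (default 40).
#' @param snp_density SNP-array marker density per Mb (default 40).
#' @param roh_length planted homozygosity length in bp around the causal
#'   recessive locus of the consanguineous diagnosed family (default 8 Mb).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_families = 35, seed = 1,
                          specs = causal_specs_default(),
                          n_background = 200, prop_common = 0.9,
                          prop_in_panel = 0.15, low_depth_rate = 0.05,
                          n_controls = 8, n_artifacts = 8,
                          n_panel_decoys = 40, snp_density = 40,
                          roh_length = 8e6) {
  if (is.null(seed)) abort("a seed is mandatory")
  if (n_families < nrow(specs)) {
    abort("more causal specs than families")
  }
  if (snp_density <= 0) abort("snp_density must be positive")
  structure(as.list(environment()), class = "cohort_config")
}

table1_path <- function() {
  system.file("extdata", "table1_phenotypes.tsv", package = "wesdx",
              mustWork = TRUE)
}

#' The packaged 38-patient phenotype fixture
#' @return phenotype tibble (see [read_phenotypes()]).
#' @export
table1_phenotypes <- function() {
  read_phenotypes(table1_path())
}

spec_family_id <- function(index) sprintf("F%02d", index)

# pedigree for the fixture cohort: every family gets both parents
# (ungenotyped unless a segregation plan names them); the dominant family
# with maternal transmission gets an affected mother and an unaffected
# maternal aunt; the recessive sib-pair family two unaffected sibs
build_pedigree <- function(phenotypes, specs) {
  rows <- list()
  for (fam in unique(phenotypes$family_id)) {
    ph <- phenotypes[phenotypes$family_id == fam, ]
    fa <- paste0(fam, "_fa"); mo <- paste0(fam, "_mo")
    spec <- specs[spec_family_id(specs$family_index) == fam, ]
    plan <- if (nrow(spec) == 1) spec$segregation_plan else ""
    rows[[fam]] <- bind_rows(
      tibble(family_id = fam, individual_id = ph$individual_id,
             father_id = fa, mother_id = mo, sex = ph$sex,
             affected = TRUE,
             consanguineous_parents = ph$consanguineous_parents),
      tibble(family_id = fam,
             individual_id = c(fa, mo),
             father_id = NA_character_, mother_id = NA_character_,
             sex = c("male", "female"),
             affected = c(FALSE, identical(plan, "affected_mother_aunt")),
             consanguineous_parents = FALSE),
      if (identical(plan, "affected_mother_aunt")) {
        tibble(family_id = fam, individual_id = paste0(fam, "_aunt"),
               father_id = NA_character_, mother_id = NA_character_,
               sex = "female", affected = FALSE,
               consanguineous_parents = FALSE)
      },
      if (identical(plan, "parents_and_sibs")) {
        tibble(family_id = fam,
               individual_id = paste0(fam, c("_s1", "_s2")),
               father_id = fa, mother_id = mo,
               sex = c("male", "female"), affected = FALSE,
               consanguineous_parents = ph$consanguineous_parents[1])
      }
    )
  }
  validate_pedigree(bind_rows(rows))
}

build_panel <- function(specs, n_decoys) {
  causal <- specs |>
    distinct(.data$gene, .data$disorder, .keep_all = TRUE) |>
    transmute(
      gene = .data$gene,
      hpo_terms = map(.data$gene, ~c("HP:0000252", "HP:0011451")),
      disorder = .data$disorder,
      inheritance_modes = map(.data$model, ~unname(candidate_mode(.x)))
    )
  if (n_decoys > 0) {
    decoys <- tibble(
      gene = sprintf("PNL%03d", seq_len(n_decoys)),
      # half the decoys carry a query term (they pass the phenotype filter),
      # half only non-query neurodevelopmental terms
      hpo_terms = map(seq_len(n_decoys), function(i) {
        if (i %% 2 == 0) c("HP:0000252", "HP:0002011") else
          c("HP:0000252", "HP:0001250")
      }),
      disorder = sprintf("Synthetic panel disorder %03d", seq_len(n_decoys)),
      inheritance_modes = map(seq_len(n_decoys), function(i) {
        c("AR", "AD", "XL")[1 + (i %% 3)]
      })
    )
    causal <- bind_rows(causal, decoys)
  }
  causal
}

build_known_pathogenic <- function(specs) {
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    vs <- specs$variants[[i]][[1]]
    kp <- vs[vs$known_pathogenic, ]
    if (nrow(kp) > 0) {
      rows[[length(rows) + 1]] <- tibble(
        chrom = specs$chrom[i], pos = kp$pos, ref = kp$ref, alt = kp$alt,
        gene = specs$gene[i], disorder = specs$disorder[i])
    }
  }
  # decoy entries in genes outside the panel exercise the fallback path
  decoys <- tibble(
    chrom = c("7", "11", "MT"), pos = c(55242465L, 17418477L, 3243L),
    ref = c("G", "C", "A"), alt = c("A", "T", "G"),
    gene = c("KPD001", "KPD002", "MT-TL1"),
    disorder = c("Synthetic lookup disorder 1", "Synthetic lookup disorder 2",
                 "Synthetic lookup disorder 3"))
  bind_rows(bind_rows(rows), decoys)
}

draw_consequence <- function(n) {
  sample(consequence_classes(), n, replace = TRUE,
         prob = c(0.03, 0.01, 0.01, 0.50, 0.30, 0.05, 0.10))
}

draw_predictions <- function(consequence) {
  algs <- prediction_algorithms()
  if (consequence != "missense") return(setNames(character(0), character(0)))
  n_del <- sample(0:4, 1, prob = c(0.35, 0.25, 0.2, 0.12, 0.08))
  verdicts <- c(rep("deleterious", n_del),
                sample(c("tolerated", "unknown"), 4 - n_del, replace = TRUE))
  setNames(verdicts[seq_along(algs)], algs)
}

causal_predictions <- function(n_del) {
  algs <- prediction_algorithms()
  setNames(c(rep("deleterious", n_del),
             rep("unknown", length(algs) - n_del)), algs)
}

bases <- c("A", "C", "G", "T")

random_allele_pair <- function() {
  ref <- sample(bases, 1)
  alt <- sample(setdiff(bases, ref), 1)
  c(ref, alt)
}

background_variant <- function(config, panel_genes, family_id, patients) {
  chrom <- sample(c(as.character(1:22), "X"),
                  1, prob = c(rep(1, 22), 0.6))
  pair <- random_allele_pair()
  common <- runif(1) < config$prop_common
  freqs <- if (common) {
    base <- runif(1, 0.05, 0.5)
    af <- pmin(pmax(base + runif(6, -0.02, 0.02), 0.001), 0.999)
    setNames(af, freq_databases())
  } else if (runif(1) < 0.5) {
    dbs <- sample(freq_databases(), sample(1:3, 1))
    setNames(runif(length(dbs), 0, 0.019), dbs)
  } else {
    setNames(numeric(0), character(0))
  }
  gene <- if (runif(1) < config$prop_in_panel) {
    sample(panel_genes, 1)
  } else {
    sprintf("BGG%04d", sample.int(3000, 1))
  }
  csq <- draw_consequence(1)
  low_depth <- runif(1) < config$low_depth_rate
  gts <- vapply(patients, function(p) {
    sample(c("hom_ref", "het", "hom_alt"), 1, prob = c(0.25, 0.6, 0.15))
  }, "")
  if (all(gts == "hom_ref")) gts[1] <- "het"
  dps <- setNames(
    if (low_depth) sample(0:4, length(patients), replace = TRUE)
    else rpois(length(patients), 60) + 5,
    patients)
  variant_row(
    chrom = chrom, pos = sample.int(2.4e8, 1), ref = pair[1], alt = pair[2],
    gene = gene, consequence = csq,
    pop_freqs = freqs, pred = draw_predictions(csq),
    known_pathogenic = FALSE, sanger_confirmed = FALSE,
    gt = gts, dp = dps)
}

causal_genotypes <- function(model, patients, sexes) {
  switch(model,
         AR_hom = setNames(rep("hom_alt", length(patients)), patients),
         AR_comphet = setNames(rep("het", length(patients)), patients),
         AD = setNames(rep("het", length(patients)), patients),
         XL = setNames(ifelse(sexes == "male", "hemi", "het"), patients))
}

causal_variant_rows <- function(spec, patients, sexes) {
  vs <- spec$variants[[1]][[1]]
  rows <- list()
  for (j in seq_len(nrow(vs))) {
    freqs <- if (!is.na(vs$af_exac[j])) c(ExAC = vs$af_exac[j]) else
      setNames(numeric(0), character(0))
    rows[[j]] <- variant_row(
      chrom = spec$chrom, pos = vs$pos[j], ref = vs$ref[j], alt = vs$alt[j],
      gene = spec$gene, consequence = vs$consequence[j],
      pop_freqs = freqs,
      pred = if (vs$n_deleterious_preds[j] > 0)
        causal_predictions(vs$n_deleterious_preds[j]) else
          setNames(character(0), character(0)),
      known_pathogenic = vs$known_pathogenic[j],
      sanger_confirmed = TRUE,
      gt = causal_genotypes(spec$model, patients, sexes),
      dp = setNames(sample(20:100, length(patients), replace = TRUE), patients))
  }
  bind_rows(rows)
}

# Sanger genotypes of additional relatives per segregation plan
relative_genotypes_for <- function(spec, fam) {
  vs <- spec$variants[[1]][[1]]
  fa <- paste0(fam, "_fa"); mo <- paste0(fam, "_mo")
  key <- function(j) tibble(family_id = fam, chrom = spec$chrom,
                            pos = vs$pos[j], ref = vs$ref[j], alt = vs$alt[j])
  plan <- spec$segregation_plan
  rows <- list()
  add <- function(j, id, gt) {
    rows[[length(rows) + 1]] <<- mutate(key(j), individual_id = id, gt = gt)
  }
  if (plan == "parents" || plan == "parents_and_sibs") {
    if (spec$model == "AR_hom") {
      add(1, fa, "het"); add(1, mo, "het")
    } else {  # comphet: allele 1 paternal, allele 2 maternal
      add(1, fa, "het"); add(1, mo, "hom_ref")
      add(2, fa, "hom_ref"); add(2, mo, "het")
    }
    if (plan == "parents_and_sibs") {
      add(1, paste0(fam, "_s1"), "het"); add(2, paste0(fam, "_s1"), "hom_ref")
      add(1, paste0(fam, "_s2"), "hom_ref"); add(2, paste0(fam, "_s2"), "hom_ref")
    }
  } else if (plan == "affected_mother_aunt") {
    add(1, mo, "het"); add(1, paste0(fam, "_aunt"), "hom_ref")
  } else if (plan == "mother_negative") {
    add(1, mo, "hom_ref")
  } else if (plan == "parents_negative") {
    add(1, fa, "hom_ref"); add(1, mo, "hom_ref")
  }
  bind_rows(rows) |>
    select("family_id", "individual_id", "chrom", "pos", "ref", "alt", "gt")
}

#' Generate a single-sample SNP-array genotype track
#'
#' Marker positions are drawn uniformly over the region at the requested
#' density; outside any planted run of homozygosity, genotypes are
#' Hardy-Weinberg draws at a per-SNP minor-allele frequency uniform on
#' 5-50 %, so the expected heterozygosity per SNP is `2p(1-p)`. Inside a
#' planted run every call is homozygous (autozygous single-allele draw).
#'
#' @param chrom chromosome label.
#' @param region_start,region_end covered region (1-based, inclusive).
#' @param density markers per Mb (must be positive).
#' @param roh optional `c(start, end)` planted homozygous stretch.
#' @param no_call_rate per-SNP missingness (default 0.005).
#' @return tibble `chrom`, `pos`, `genotype` (caller assigns `sample`).
#' @export
generate_snp_track <- function(chrom, region_start, region_end, density,
                               roh = NULL, no_call_rate = 0.005) {
  if (density <= 0) abort("SNP density must be positive")
  if (!is.null(roh)) {
    if (roh[1] < region_start || roh[2] > region_end) {
      abort("planted ROH exceeds the simulated region")
    }
  }
  n <- max(2L, round((region_end - region_start + 1) / 1e6 * density))
  pos <- sort(sample(seq.int(region_start, region_end), n))
  maf <- runif(n, 0.05, 0.5)
  g <- character(n)
  u <- runif(n)
  hom_b <- maf^2
  het <- 2 * maf * (1 - maf)
  g[u < hom_b] <- "BB"
  g[u >= hom_b & u < hom_b + het] <- "AB"
  g[u >= hom_b + het] <- "AA"
  if (!is.null(roh)) {
    inside <- pos >= roh[1] & pos <= roh[2]
    g[inside] <- ifelse(runif(sum(inside)) < maf[inside], "BB", "AA")
  }
  g[runif(n) < no_call_rate] <- "no_call"
  tibble(chrom = as.character(chrom), pos = as.integer(pos), genotype = g)
}

#' Generate a pair of sibling tracks with a planted shared segment
#'
#' Outside the shared segment the two genotypes are independent
#' Hardy-Weinberg draws; inside, the sharing mode is enforced per SNP:
#' `"hom"` — identical homozygous genotype; `"combination"` — identical
#' genotype (heterozygous allowed); `"one_allele"` — at least one allele in
#' common.
#'
#' @inheritParams generate_snp_track
#' @param shared `c(start, end)` planted shared segment, or `NULL`.
#' @param mode `"hom"`, `"combination"` or `"one_allele"`.
#' @return list of two track tibbles on identical positions.
#' @export
generate_sib_pair_tracks <- function(chrom, region_start, region_end, density,
                                     shared = NULL, mode = "combination",
                                     no_call_rate = 0.005) {
  a <- generate_snp_track(chrom, region_start, region_end, density,
                          no_call_rate = 0)
  b <- generate_snp_track(chrom, region_start, region_end, density,
                          no_call_rate = 0)
  b$pos <- a$pos
  if (!is.null(shared)) {
    inside <- which(a$pos >= shared[1] & a$pos <= shared[2])
    if (mode == "hom") {
      hom <- sample(c("AA", "BB"), length(inside), replace = TRUE, prob = c(0.6, 0.4))
      a$genotype[inside] <- hom
      b$genotype[inside] <- hom
    } else if (mode == "combination") {
      b$genotype[inside] <- a$genotype[inside]
    } else if (mode == "one_allele") {
      shared_allele <- sample(c("A", "B"), length(inside), replace = TRUE)
      other <- function() sample(c("A", "B"), length(inside), replace = TRUE)
      mk <- function(extra) {
        al <- rbind(shared_allele, extra)
        apply(al, 2, function(x) paste(sort(x), collapse = ""))
      }
      a$genotype[inside] <- mk(other())
      b$genotype[inside] <- mk(other())
    } else {
      abort("unknown sharing mode")
    }
  }
  n <- nrow(a)
  a$genotype[runif(n) < no_call_rate] <- "no_call"
  b$genotype[runif(n) < no_call_rate] <- "no_call"
  list(a = a, b = b)
}

#' Generate the full cohort bundle
#'
#' @param config a [cohort_config()].
#' @return a `cohort_bundle` list: `pedigree`, `phenotypes`, `panel`,
#'   `known_pathogenic`, `variants` (variant table with `family_id`),
#'   `relatives`, `controls`, `snp_tracks`, `truth`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  specs <- config$specs

  if (config$n_families == 35) {
    phenotypes <- table1_phenotypes()
  } else {
    n <- config$n_families
    specs$family_index <- seq_len(nrow(specs))
    # the X-linked de novo spec needs a female proband
    sexes <- sample(c("male", "female"), n, replace = TRUE)
    xl <- specs$family_index[specs$model == "XL"]
    sexes[xl] <- "female"
    phenotypes <- tibble(
      family_id = spec_family_id(seq_len(n)),
      individual_id = sprintf("P%02d", seq_len(n)),
      age_years = round(runif(n, 0, 20)),
      sex = sexes,
      ofc_z = round(runif(n, -8, -3), 1),
      consanguineous_parents = FALSE,
      affected = TRUE,
      hpo_terms = map(seq_len(n), ~c("HP:0000252", "HP:0001249"))
    )
  }

  pedigree <- build_pedigree(phenotypes, specs)
  panel <- build_panel(specs, config$n_panel_decoys)
  known <- build_known_pathogenic(specs)
  panel_genes <- panel$gene

  fams <- unique(phenotypes$family_id)
  spec_fam <- spec_family_id(specs$family_index)

  # recurrent same-run artifacts: identical alleles in every patient and in
  # all control samples
  artifact_sites <- tibble(
    chrom = sample(as.character(1:22), config$n_artifacts, replace = TRUE),
    pos = sample.int(2.4e8, config$n_artifacts),
    ref = vapply(seq_len(config$n_artifacts), function(i) sample(bases, 1), ""),
    consequence = draw_consequence(config$n_artifacts))
  artifact_sites$alt <- vapply(artifact_sites$ref, function(r) {
    sample(setdiff(bases, r), 1)
  }, "")
  # plus low-recurrence control alleles (3 of the controls): below the
  # default artifact threshold, so they survive the control filter
  lowrec_sites <- tibble(
    chrom = sample(as.character(1:22), 4, replace = TRUE),
    pos = sample.int(2.4e8, 4),
    ref = vapply(1:4, function(i) sample(bases, 1), ""))
  lowrec_sites$alt <- vapply(lowrec_sites$ref, function(r) {
    sample(setdiff(bases, r), 1)
  }, "")

  controls <- bind_rows(
    tidyr::crossing(sample = sprintf("CTL%02d", seq_len(config$n_controls)),
                    artifact_sites[, c("chrom", "pos", "ref", "alt")]),
    tidyr::crossing(sample = sprintf("CTL%02d", 1:3),
                    lowrec_sites[, c("chrom", "pos", "ref", "alt")])
  ) |> arrange(.data$sample, .data$chrom, .data$pos)

  variants <- list()
  relatives <- list()
  truth_rows <- list()
  for (fam in fams) {
    ph <- phenotypes[phenotypes$family_id == fam, ]
    patients <- ph$individual_id
    sexes <- ph$sex
    fam_vars <- bind_rows(map(seq_len(config$n_background), function(i) {
      background_variant(config, panel_genes, fam, patients)
    }))
    art <- bind_rows(map(seq_len(nrow(artifact_sites)), function(i) {
      variant_row(
        chrom = artifact_sites$chrom[i], pos = artifact_sites$pos[i],
        ref = artifact_sites$ref[i], alt = artifact_sites$alt[i],
        gene = sprintf("ARTG%02d", i), consequence = artifact_sites$consequence[i],
        gt = setNames(rep("het", length(patients)), patients),
        dp = setNames(rpois(length(patients), 60) + 5, patients))
    }))
    lowrec <- bind_rows(map(seq_len(nrow(lowrec_sites)), function(i) {
      variant_row(
        chrom = lowrec_sites$chrom[i], pos = lowrec_sites$pos[i],
        ref = lowrec_sites$ref[i], alt = lowrec_sites$alt[i],
        gene = sprintf("LRG%02d", i), consequence = "missense",
        gt = setNames(rep("het", length(patients)), patients),
        dp = setNames(rpois(length(patients), 60) + 5, patients))
    }))
    fam_vars <- bind_rows(fam_vars, art, lowrec)
    si <- which(spec_fam == fam)
    if (length(si) == 1) {
      spec <- specs[si, ]
      cv <- causal_variant_rows(spec, patients, sexes)
      fam_vars <- bind_rows(fam_vars, cv)
      rel <- relative_genotypes_for(spec, fam)
      if (nrow(rel) > 0) relatives[[fam]] <- rel
      truth_rows[[fam]] <- tibble(
        family_id = fam, gene = spec$gene, model = spec$model,
        keys = paste(variant_key(cv), collapse = ";"),
        n_affected = length(patients))
    }
    fam_vars$family_id <- fam
    fam_vars <- fam_vars |>
      arrange(.data$chrom, .data$pos, .data$alt) |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE)
    variants[[fam]] <- fam_vars
  }
  variants <- bind_rows(variants)
  relatives <- if (length(relatives) > 0) bind_rows(relatives) else
    tibble(family_id = character(), individual_id = character(),
           chrom = character(), pos = integer(), ref = character(),
           alt = character(), gt = character())

  # SNP-array tracks: single-patient ROH mapping for the consanguineous
  # recessive-homozygous diagnosis, plus the three sib-pair sharing modes
  roh_spec <- specs[specs$model == "AR_hom" & specs$segregation_plan == "parents" &
                      specs$gene == "ERCC8", ]
  tracks <- list()
  truth_roh <- tibble(sample = character(), chrom = character(),
                      start = integer(), end = integer(), mode = character())
  if (nrow(roh_spec) == 1 && spec_family_id(roh_spec$family_index) %in% fams) {
    fam <- spec_family_id(roh_spec$family_index)
    patient <- phenotypes$individual_id[phenotypes$family_id == fam][1]
    locus <- roh_spec$variants[[1]][[1]]$pos[1]
    half <- config$roh_length / 2
    roh <- c(as.integer(locus - half), as.integer(locus + half - 1))
    tr <- generate_snp_track(roh_spec$chrom, locus - 25e6, locus + 25e6,
                             config$snp_density, roh = roh)
    tr$sample <- patient
    tracks[[length(tracks) + 1]] <- tr
    truth_roh <- bind_rows(truth_roh, tibble(
      sample = patient, chrom = roh_spec$chrom,
      start = roh[1], end = roh[2], mode = "single_roh"))
  }
  sib_fams <- phenotypes |> count(.data$family_id) |> filter(.data$n == 2)
  ar_fams <- spec_fam[specs$model %in% c("AR_hom", "AR_comphet")]
  for (k in seq_len(nrow(sib_fams))) {
    fam <- sib_fams$family_id[k]
    sibs <- phenotypes$individual_id[phenotypes$family_id == fam]
    # consanguineous sibs: shared homozygosity; sibs with a recessive
    # disorder: shared allele combination; otherwise (dominant suspicion):
    # at least one shared allele
    consang <- any(phenotypes$consanguineous_parents[
      phenotypes$family_id == fam])
    mode <- if (consang) "hom" else if (fam %in% ar_fams) "combination"
      else "one_allele"
    shared <- c(40e6, 48e6)
    pair <- generate_sib_pair_tracks("9", 20e6, 70e6, config$snp_density,
                                     shared = shared, mode = mode)
    pair$a$sample <- sibs[1]
    pair$b$sample <- sibs[2]
    tracks[[length(tracks) + 1]] <- pair$a
    tracks[[length(tracks) + 1]] <- pair$b
    truth_roh <- bind_rows(truth_roh, tibble(
      sample = paste(sibs, collapse = ","), chrom = "9",
      start = as.integer(shared[1]), end = as.integer(shared[2]),
      mode = c(hom = "sibs_shared_hom", combination = "recessive_shared",
               one_allele = "dominant_shared")[[mode]]))
  }
  snp_tracks <- bind_rows(tracks) |>
    select("sample", "chrom", "pos", "genotype")

  truth <- list(
    seed = config$seed,
    causal = bind_rows(truth_rows),
    roh = truth_roh
  )
  structure(list(
    pedigree = pedigree, phenotypes = phenotypes, panel = panel,
    known_pathogenic = known, variants = variants, relatives = relatives,
    controls = controls, snp_tracks = snp_tracks, truth = truth,
    config = config
  ), class = "cohort_bundle")
}

#' Write a cohort bundle to disk
#'
#' Produces the exact formats the readers consume: `pedigree.ped`,
#' `phenotypes.tsv`, `panel.tsv`, `known_pathogenic.tsv`, `controls.tsv`,
#' `relatives.tsv`, `snp_tracks.tsv`, `truth.json` and one decomposed
#' biallelic VCF per family under `vcf/`.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_ped(bundle$pedigree, file.path(dir, "pedigree.ped"))
  write_phenotypes(bundle$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_gene_panel(bundle$panel, file.path(dir, "panel.tsv"))
  write_simple_tsv(bundle$known_pathogenic, file.path(dir, "known_pathogenic.tsv"))
  write_simple_tsv(bundle$controls, file.path(dir, "controls.tsv"))
  write_simple_tsv(bundle$relatives, file.path(dir, "relatives.tsv"))
  write_simple_tsv(bundle$snp_tracks, file.path(dir, "snp_tracks.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (fam in unique(bundle$variants$family_id)) {
    fv <- bundle$variants[bundle$variants$family_id == fam, ]
    samples <- bundle$phenotypes$individual_id[
      bundle$phenotypes$family_id == fam]
    write_vcf(select(fv, -"family_id"), file.path(dir, "vcf", paste0(fam, ".vcf")),
              samples = samples)
  }
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' @param dir directory written by [write_cohort()] (or real data in the
#'   same layout).
#' @return a `cohort_bundle` list (without `config`; `truth` only if
#'   `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  pedigree <- read_ped(file.path(dir, "pedigree.ped"))
  phenotypes <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  panel <- read_gene_panel(file.path(dir, "panel.tsv"))
  known <- read_known_pathogenic(file.path(dir, "known_pathogenic.tsv"))
  controls <- read_tsv_quiet(file.path(dir, "controls.tsv"),
                             col_types = readr::cols(
                               sample = "c", chrom = "c", pos = "i",
                               ref = "c", alt = "c"))
  relatives_path <- file.path(dir, "relatives.tsv")
  relatives <- if (file.exists(relatives_path)) {
    read_tsv_quiet(relatives_path, col_types = readr::cols(
      family_id = "c", individual_id = "c", chrom = "c", pos = "i",
      ref = "c", alt = "c", gt = "c"))
  } else NULL
  tracks_path <- file.path(dir, "snp_tracks.tsv")
  snp_tracks <- if (file.exists(tracks_path)) read_snp_tracks(tracks_path) else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path) else NULL
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  variants <- bind_rows(map(vcfs, function(path) {
    fam <- sub("\\.vcf$", "", basename(path))
    v <- read_vcf(path, pedigree)
    if (nrow(v) > 0) v$family_id <- fam
    v
  }))
  structure(list(
    pedigree = pedigree, phenotypes = phenotypes, panel = panel,
    known_pathogenic = known, variants = variants, relatives = relatives,
    controls = controls, snp_tracks = snp_tracks, truth = truth
  ), class = "cohort_bundle")
}
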