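#' Variant filter cascade
#'
#' The prioritization cascade applied per family, in fixed order:
#'
#' 1. **Read depth** — remove variants covered by fewer than `min_reads`
#'    sequence reads in any affected carrier (default 5).
#' 2. **Population frequency** — remove possibly benign variants with an
#'    allele frequency above `max_af` (default 2 %) in at least one of the
#'    consulted databases (default dbSNP, 1000G, Seattle, GoNL). An allele
#'    absent from a database is *not observed*, never grounds for removal.
#' 3. **Run controls** — remove alleles also called in at least
#'    `control_min_count` of the control samples sequenced on the same run
#'    (sequencing artifacts; default 4 of 8).
#' 4. **Phenotype panel** — split the survivors into variants in panel genes
#'    annotated with at least one of the query HPO terms (*matched*) and the
#'    rest (*unmatched*). Unmatched variants are retained for the
#'    known-pathogenic fallback, not discarded.
#'
#' Every stage records `(stage, n_in, n_removed, n_out)` in a `FilterTrace`
#' tibble; counts are conserved (`n_out = n_in - n_removed`, and stage k+1
#' starts from stage k's output).
#'
#' @name filter-cascade
NULL

#' Cascade configuration
#'
#' @param min_reads minimum read depth in every affected carrier (default 5).
#' @param max_af maximum tolerated allele frequency (default 0.02); removal
#'   is strict (`AF > max_af`), so 2.0 % exactly survives.
#' @param databases databases consulted by the frequency filter.
#' @param control_min_count minimum number of same-run control samples
#'   carrying the identical allele for it to count as an artifact.
#' @param hpo_query_terms HPO terms defining the phenotype of interest
#'   (default: microcephaly, nervous-system and head abnormality terms).
#' @param ontology optional HPO ancestor map from [read_hpo_ontology()];
#'   when supplied, a panel term matches a query term if it equals it or is
#'   one of its descendants; plain set intersection otherwise.
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(min_reads = 5,
                           max_af = 0.02,
                           databases = c("dbSNP", "1000G", "Seattle", "GoNL"),
                           control_min_count = 4,
                           hpo_query_terms = c("HP:0011451", "HP:0005484",
                                               "HP:0000253", "HP:0002011",
                                               "HP:0000707", "HP:0000234"),
                           ontology = NULL) {
  if (min_reads < 0) abort("min_reads must be >= 0")
  if (max_af < 0 || max_af > 1) abort("max_af must lie in [0, 1]")
  structure(list(min_reads = min_reads, max_af = max_af,
                 databases = databases,
                 control_min_count = control_min_count,
                 hpo_query_terms = hpo_query_terms,
                 ontology = ontology),
            class = "cascade_config")
}

#' Read a cascade configuration from a YAML block
#'
#' Recognized keys mirror the arguments of [cascade_config()]; unset keys
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return a `cascade_config` list.
#' @export
read_cascade_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(cascade_config)), "ontology")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown cascade config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(cascade_config, raw)
}

#' Minimal HPO ontology reader (OBO format)
#'
#' Parses `id:` and `is_a:` lines of `[Term]` stanzas and returns, for every
#' term, the set of itself plus all its ancestors. Only used when
#' descendant-closure matching is requested in [cascade_config()].
#'
#' @param path OBO file path.
#' @return named list: term -> character vector of the term and ancestors.
#' @export
read_hpo_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parents <- list()
  current <- NULL
  for (line in lines) {
    if (line == "[Term]") current <- NULL
    else if (startsWith(line, "id: ")) {
      current <- sub("^id: ", "", line)
      parents[[current]] <- parents[[current]] %||% character(0)
    } else if (startsWith(line, "is_a: ") && !is.null(current)) {
      p <- sub(" !.*$", "", sub("^is_a: ", "", line))
      parents[[current]] <- c(parents[[current]], p)
    }
  }
  closure <- function(term) {
    seen <- character(0)
    frontier <- term
    while (length(frontier) > 0) {
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)), seen)
    }
    seen
  }
  setNames(lapply(names(parents), closure), names(parents))
}

#' @rdname filter-cascade
#' @param variants a variant table ([variant-table]).
#' @param affected character vector of affected, sequenced individual ids in
#'   this family.
#' @param min_reads see [cascade_config()].
#' @return each `filter_*` returns `list(kept, removed)` of variant tables.
#' @export
filter_min_reads <- function(variants, affected, min_reads = 5) {
  if (nrow(variants) == 0 || min_reads == 0) {
    return(list(kept = variants, removed = variants[0, ]))
  }
  fails <- map_lgl(seq_len(nrow(variants)), function(i) {
    gts <- variants$gt[[i]]
    dps <- variants$dp[[i]]
    carriers <- intersect(affected, names(gts)[gts %in% carrier_codes()])
    if (length(carriers) == 0) return(FALSE)
    depth <- as.numeric(dps[carriers])
    depth[is.na(depth)] <- 0  # missing depth treated as 0 (and logged)
    if (any(is.na(dps[carriers]) | !(carriers %in% names(dps)))) {
      warn(paste0("missing read depth treated as 0 at ",
                  variant_key(variants[i, ])))
    }
    any(depth < min_reads)
  })
  list(kept = variants[!fails, ], removed = variants[fails, ])
}

#' @rdname filter-cascade
#' @param databases,max_af see [cascade_config()].
#' @export
filter_population_frequency <- function(variants,
                                        databases = c("dbSNP", "1000G",
                                                      "Seattle", "GoNL"),
                                        max_af = 0.02) {
  if (nrow(variants) == 0) return(list(kept = variants, removed = variants[0, ]))
  freqs <- unlist(variants$pop_freqs, use.names = FALSE)
  if (length(freqs) > 0 && any(freqs < 0)) {
    abort("negative allele frequency in input")
  }
  fails <- map_lgl(variants$pop_freqs, function(f) {
    f <- f[names(f) %in% databases]
    length(f) > 0 && any(f > max_af)
  })
  list(kept = variants[!fails, ], removed = variants[fails, ])
}

#' @rdname filter-cascade
#' @param control_variants tibble of alleles called in same-run control
#'   samples, columns `sample`, `chrom`, `pos`, `ref`, `alt`.
#' @param control_min_count see [cascade_config()].
#' @export
filter_run_controls <- function(variants, control_variants,
                                control_min_count = 4) {
  if (is.null(control_variants) || nrow(control_variants) == 0) {
    warn("no control samples supplied; run-control filter skipped")
    return(list(kept = variants, removed = variants[0, ]))
  }
  if (nrow(variants) == 0) return(list(kept = variants, removed = variants[0, ]))
  counts <- control_variants |>
    distinct(.data$sample, key = variant_key(control_variants)) |>
    count(.data$key)
  hits <- setNames(counts$n, counts$key)
  n_ctl <- unname(hits[variant_key(variants)])
  n_ctl[is.na(n_ctl)] <- 0
  fails <- n_ctl >= control_min_count
  list(kept = variants[!fails, ], removed = variants[fails, ])
}

panel_terms_by_gene <- function(panel) {
  tapply(panel$hpo_terms, panel$gene,
         function(x) unique(unlist(x, use.names = FALSE)),
         simplify = FALSE)
}

#' @rdname filter-cascade
#' @param panel gene panel ([read_gene_panel()]).
#' @param hpo_query_terms,ontology see [cascade_config()].
#' @return `filter_phenotype_panel()` returns `list(matched, unmatched)`;
#'   variants with an empty gene symbol are routed to `unmatched`.
#' @export
filter_phenotype_panel <- function(variants, panel, hpo_query_terms,
                                   ontology = NULL) {
  if (nrow(variants) == 0) return(list(matched = variants, unmatched = variants[0, ]))
  gene_terms <- panel_terms_by_gene(panel)
  term_matches <- function(panel_term) {
    if (is.null(ontology)) return(panel_term %in% hpo_query_terms)
    ancestors <- ontology[[panel_term]] %||% panel_term
    length(intersect(ancestors, hpo_query_terms)) > 0
  }
  hit <- map_lgl(variants$gene, function(g) {
    if (is.na(g) || !nzchar(g)) return(FALSE)
    terms <- gene_terms[[g]]
    if (is.null(terms)) return(FALSE)
    any(vapply(terms, term_matches, logical(1)))
  })
  list(matched = variants[hit, ], unmatched = variants[!hit, ])
}

#' @rdname filter-cascade
#' @param config a [cascade_config()].
#' @return `apply_cascade()` returns `list(matched, unmatched, removed,
#'   trace)` where `removed` carries a `filter` column naming the removing
#'   stage and `trace` is the FilterTrace tibble.
#' @export
apply_cascade <- function(variants, affected, panel,
                          control_variants = NULL,
                          config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  trace <- tibble(stage = character(), n_in = integer(),
                  n_removed = integer(), n_out = integer())
  removed_all <- list()
  step <- function(name, result, current_n) {
    trace <<- bind_rows(trace, tibble(
      stage = name, n_in = current_n,
      n_removed = nrow(result$removed), n_out = nrow(result$kept)))
    if (nrow(result$removed) > 0) {
      removed_all[[name]] <<- mutate(result$removed, filter = name)
    }
    result$kept
  }
  n0 <- nrow(variants)
  v <- step("min_reads",
            filter_min_reads(variants, affected, config$min_reads), n0)
  v <- step("population_frequency",
            filter_population_frequency(v, config$databases, config$max_af),
            nrow(v))
  v <- step("run_controls",
            filter_run_controls(v, control_variants, config$control_min_count),
            nrow(v))
  ph <- filter_phenotype_panel(v, panel, config$hpo_query_terms,
                               config$ontology)
  # the panel stage routes rather than discards: n_removed counts variants
  # diverted to the unmatched (fallback) pool
  trace <- bind_rows(trace, tibble(
    stage = "phenotype_panel", n_in = nrow(v),
    n_removed = nrow(ph$unmatched), n_out = nrow(ph$matched)))
  removed <- if (length(removed_all) > 0) bind_rows(removed_all) else
    mutate(variants[0, ], filter = character(0))
  list(matched = ph$matched, unmatched = ph$unmatched,
       removed = removed, trace = trace)
}

#' Check FilterTrace count conservation
#'
#' @param trace a FilterTrace tibble.
#' @return `TRUE` invisibly; aborts if counts are inconsistent.
#' @export
validate_trace <- function(trace) {
  if (any(trace$n_out != trace$n_in - trace$n_removed) || any(trace$n_out < 0)) {
    abort("FilterTrace: n_out must equal n_in - n_removed and be >= 0")
  }
  if (nrow(trace) > 1 &&
      any(trace$n_in[-1] != trace$n_out[-nrow(trace)])) {
    abort("FilterTrace: stage k+1 must start from stage k's output")
  }
  invisible(TRUE)
}
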