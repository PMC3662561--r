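# Fixtures built in code and independent oracles used across test files.

# Tiny deterministic cohort: 4 populations x 6 individuals, small SNP pool,
# small panel. Everything downstream of simulate_cohort() is exercised.
toy_cohort <- function(seed = 101, n_pool_snps = 800, panel_snps = 6,
                       n_per_pop = 6, event = NULL,
                       phenotype_fraction = 0.4, ...) {
  suppressMessages(suppressWarnings(simulate_cohort(
    n_populations = 4, n_per_pop = n_per_pop, n_pool_snps = n_pool_snps,
    drift_f = 0.05, panel_snps = panel_snps, event = event, seed = seed,
    phenotype_fraction = phenotype_fraction, ...
  )))
}

# Hand-built genotype matrix from a list of per-individual call vectors.
hand_genotypes <- function(calls_by_ind, populations, snp_ids = NULL,
                           counted = NULL) {
  calls <- do.call(rbind, calls_by_ind)
  rownames(calls) <- names(calls_by_ind)
  colnames(calls) <- snp_ids %||% sprintf("s%d", seq_len(ncol(calls)))
  genotype_matrix(calls, setNames(populations, names(calls_by_ind)), counted)
}

# A minimal one-disease panel with given per-genotype L values (lr0 =
# hom-protective, lr2 = hom-risk) on SNPs assumed counted/risk allele "A".
hand_panel <- function(snp_ids, lr0, lr1, lr2, risk_is_minor = TRUE,
                       maf = 0.3, category = "missense") {
  n <- length(snp_ids)
  panel <- tibble::tibble(
    snp_id = snp_ids,
    risk_allele = "A",
    risk_is_minor = rep_len(risk_is_minor, n),
    lr0 = rep_len(lr0, n), lr1 = rep_len(lr1, n), lr2 = rep_len(lr2, n),
    n_studies = 1L,
    global_maf = rep_len(maf, n),
    functional_category = rep_len(category, n)
  )
  structure(panel, disease = "toy", class = c("disease_panel", class(panel)))
}

# Independent oracle for best_event_set: recursive enumeration over
# admissible subsets working directly from descendant tip sets, with the
# same tie-breaking (max likelihood, then fewer explained, then
# lexicographic on the sorted id string).
oracle_best_event_set <- function(p, branches, y) {
  ids <- branches$branch
  sets <- branches$descendants
  n <- length(ids)
  is_related <- function(i, j) {
    all(sets[[i]] %in% sets[[j]]) || all(sets[[j]] %in% sets[[i]])
  }
  explained_of <- function(chosen) {
    expl <- chosen
    for (i in seq_len(n)) {
      for (z in chosen) {
        if (i != z && all(sets[[i]] %in% sets[[z]]) &&
            length(sets[[i]]) < length(sets[[z]])) {
          expl <- union(expl, i)
        }
      }
    }
    expl
  }
  best <- NULL
  rec <- function(start, chosen) {
    if (length(chosen) == y) {
      expl <- explained_of(chosen)
      l <- sum(log(p[ids[setdiff(seq_len(n), expl)]]))
      cand <- list(l = l, n_expl = length(expl),
                   key = paste(sort(ids[chosen]), collapse = "|"),
                   events = sort(ids[chosen]))
      if (is.null(best) || cand$l > best$l + 1e-12 ||
          (abs(cand$l - best$l) <= 1e-12 &&
           (cand$n_expl < best$n_expl ||
            (cand$n_expl == best$n_expl && cand$key < best$key)))) {
        best <<- cand
      }
      return(invisible())
    }
    if (start > n) return(invisible())
    for (i in start:n) {
      if (all(!vapply(chosen, function(z) is_related(i, z), logical(1)))) {
        rec(i + 1, c(chosen, i))
      }
      # i skipped
    }
    invisible()
  }
  rec(1, integer(0))
  best
}

# From-scratch recomputation of one null draw: build the replaced panel
# as a fresh disease_panel (inheriting L, orienting the replacement's
# risk allele to match the original's major/minor status) and score it
# with individual_risk(). Used as the literal-count oracle for the null
# matrix engine.
recompute_draw_deviation <- function(genotypes, panel, replacement_ids,
                                     plus_sets, minus_sets) {
  f <- pooled_frequency(genotypes)[replacement_ids]
  # replacement risk allele: its own minor allele when the original risk
  # allele was minor, else its major allele (counted allele is "A")
  minor_allele <- ifelse(f <= 0.5, "A", "B")
  major_allele <- ifelse(f <= 0.5, "B", "A")
  repl <- panel
  repl$snp_id <- replacement_ids
  repl$risk_allele <- ifelse(panel$risk_is_minor, minor_allele, major_allele)
  repl <- structure(repl, disease = "redraw",
                    class = c("disease_panel", class(tibble::tibble())))
  scores <- suppressWarnings(individual_risk(genotypes, repl))
  vapply(seq_along(plus_sets), function(i) {
    mean(scores$risk[scores$population %in% plus_sets[[i]]]) -
      mean(scores$risk[scores$population %in% minus_sets[[i]]])
  }, numeric(1))
}

expect_no_message_pattern <- function(object, pattern) {
  expect_false(any(grepl(pattern, capture_messages(object))))
}
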