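# The matched-SNP resampling null and the branch differentiation test.
#
# The observed statistic for a branch is the difference between the mean
# individual risk of the populations above the branch (ancestral set) and
# the mean below it (descendant set). Under the null, each panel SNP is
# replaced by a random genotyped SNP matched on global-MAF bin and
# functional category, with the replacement oriented so that its risk
# allele has the same major/minor status as the original's; the original
# SNP's combined likelihood ratios are inherited, so only the allele
# frequency structure is randomised. One replacement panel is shared by
# all branches within a draw, preserving the correlation of risk among
# related populations.

#' Matched resampling pools per panel SNP
#'
#' For each panel SNP, the candidate replacements are all annotated SNPs
#' sharing its global-MAF bin and functional category. The panel SNP
#' itself is excluded from its own pool so the observed statistic cannot
#' contaminate its null.
#'
#' @param panel A `disease_panel`.
#' @param annotations Annotation tibble covering the genotyped pool.
#' @param maf_bin Width of the global-MAF matching bins (default 0.02).
#' @return Named list (by panel SNP id) of candidate SNP id vectors.
#' @export
matched_pools <- function(panel, annotations, maf_bin = 0.02) {
  ann_bin <- maf_bin_index(annotations$global_maf, maf_bin)
  panel_bin <- maf_bin_index(panel$global_maf, maf_bin)
  pools <- lapply(seq_len(nrow(panel)), function(i) {
    idx <- ann_bin == panel_bin[i] &
      annotations$functional_category == panel$functional_category[i] &
      annotations$snp_id != panel$snp_id[i]
    annotations$snp_id[idx]
  })
  names(pools) <- panel$snp_id
  empty <- lengths(pools) == 0
  if (any(empty)) {
    i <- which(empty)[1]
    abort(sprintf(
      "empty matched pool for SNP %s (MAF bin %d, category %s)",
      panel$snp_id[i], panel_bin[i], panel$functional_category[i]))
  }
  pools
}

#' Draw one matched random panel
#'
#' Replaces every panel SNP by a uniform draw from its matched pool. The
#' replacement keeps the original SNP's combined likelihood ratios and
#' major/minor risk-allele status.
#'
#' @param panel A `disease_panel`.
#' @param pools Matched pools from [matched_pools()].
#' @param seed Optional integer seed.
#' @return The panel tibble with a `replacement_snp` column.
#' @export
draw_null_panel <- function(panel, pools, seed = NULL) {
  pools <- pools[panel$snp_id]
  repl <- with_seed_or_not(seed, vapply(pools, function(p) {
    p[sample.int(length(p), 1L)]
  }, character(1)))
  dplyr::mutate(tibble::as_tibble(panel), replacement_snp = unname(repl))
}

# Contrast matrix over individuals: one row per tested unit, +1/n over the
# "ancestral" (or focal-complement) members, -1/n over the "descendant"
# (or focal) members. O = A %*% individual risks.
contrast_matrix <- function(plus_sets, minus_sets, population, unit_names) {
  n <- length(population)
  A <- matrix(0, nrow = length(plus_sets), ncol = n,
              dimnames = list(unit_names, names(population)))
  for (i in seq_along(plus_sets)) {
    up <- population %in% plus_sets[[i]]
    dn <- population %in% minus_sets[[i]]
    if (!any(up) || !any(dn)) {
      abort(sprintf("unit %s has an empty population set", unit_names[i]))
    }
    A[i, up] <- 1 / sum(up)
    A[i, dn] <- -1 / sum(dn)
  }
  A
}

# Core engine: branch/population deviations for K shared random panels.
# Returns values (units x K) and, optionally, the drawn SNP ids
# (panel slots x K) for oracle recomputation.
null_deviations <- function(A, genotypes, panel, pools, K, seed = NULL,
                            keep_draws = FALSE) {
  pools <- pools[panel$snp_id]
  pool_ids <- unique(unlist(pools, use.names = FALSE))
  calls <- genotypes$calls[, pool_ids, drop = FALSE]
  f_pool <- colMeans(calls, na.rm = TRUE) / 2
  # copies of the pool SNP's minor allele (orientation reference)
  minor_counts <- calls
  flip <- which(f_pool > 0.5)
  if (length(flip) > 0) {
    minor_counts[, flip] <- 2L - minor_counts[, flip, drop = FALSE]
  }
  U <- lapply(0:2, function(g) {
    ind <- minor_counts == g
    ind[is.na(ind)] <- FALSE
    A %*% ind                                     # units x pool SNPs
  })
  pool_index <- lapply(pools, function(p) match(p, pool_ids))
  # per-slot log-L triplet applied to 0/1/2 minor-allele copies of the
  # replacement: flipped when the original risk allele is the major one
  lnl <- matrix(c(log(panel$lr0), log(panel$lr1), log(panel$lr2)),
                ncol = 3)
  lnl[!panel$risk_is_minor, ] <- lnl[!panel$risk_is_minor, 3:1, drop = FALSE]
  draws <- with_seed_or_not(seed, {
    vapply(pool_index, function(idx) idx[sample.int(length(idx), K, replace = TRUE)],
           integer(K))
  })
  draws <- matrix(draws, nrow = K)                 # K x slots
  values <- matrix(0, nrow = nrow(A), ncol = K,
                   dimnames = list(rownames(A), NULL))
  for (t in seq_len(nrow(panel))) {
    s <- draws[, t]
    values <- values +
      lnl[t, 1] * U[[1]][, s, drop = FALSE] +
      lnl[t, 2] * U[[2]][, s, drop = FALSE] +
      lnl[t, 3] * U[[3]][, s, drop = FALSE]
  }
  out <- list(values = values, K = K, seed = seed)
  if (keep_draws) {
    out$draws <- matrix(pool_ids[draws], nrow = K,
                        dimnames = list(NULL, panel$snp_id))
  }
  out
}

#' Build the null matrix of branch risk differences
#'
#' Computes the `branches x K` matrix of ancestral-minus-descendant risk
#' differences under `K` matched random panels, one shared panel per
#' draw.
#'
#' @param genotypes A [genotype_matrix()].
#' @param tree Rooted population phylogeny ([ape::phylo]).
#' @param panel A `disease_panel`.
#' @param annotations Annotation tibble defining the pool.
#' @param K Number of random draws; 100,000 is feasible with a
#'   genome-scale pool, simulations here default lower.
#' @param seed Optional integer seed.
#' @param maf_bin MAF matching bin width.
#' @param keep_draws Keep the drawn SNP ids (slots x K) for auditing.
#' @return A `null_matrix` object: list with `values`, `K`, `seed`,
#'   `matched_on` and optionally `draws`.
#' @export
build_null_matrix <- function(genotypes, tree, panel, annotations, K = 2000,
                              seed = NULL, maf_bin = 0.02, keep_draws = FALSE) {
  branches <- population_branches(tree)
  check_tree_populations(tree, genotypes)
  A <- contrast_matrix(branches$ancestral, branches$descendants,
                       genotypes$population, branches$branch)
  pools <- matched_pools(panel, annotations, maf_bin)
  out <- null_deviations(A, genotypes, panel, pools, K, seed, keep_draws)
  out$matched_on <- list(maf_bin = maf_bin,
                         categories = TRUE, risk_allele_status = TRUE)
  class(out) <- "null_matrix"
  out
}

check_tree_populations <- function(tree, genotypes) {
  pops <- unique(genotypes$population)
  missing <- setdiff(tree$tip.label, pops)
  if (length(missing) > 0) {
    abort(paste0("tree leaves absent from genotype populations: ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(pops, tree$tip.label)
  if (length(extra) > 0) {
    abort(paste0("populations absent from tree: ", paste(extra, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Observed branch risk deviations
#'
#' For every testable branch, the mean individual risk over members of
#' the ancestral set minus the mean over members of the descendant set
#' (individual-weighted). `direction` reports whether risk is increased
#' or decreased in the descendants.
#'
#' @param scores Individual risks from [individual_risk()].
#' @param branches Branch table from [population_branches()].
#' @return Tibble `branch`, `observed`, `direction`.
#' @export
observed_branch_deviations <- function(scores, branches) {
  A <- contrast_matrix(branches$ancestral, branches$descendants,
                       setNames(scores$population, scores$individual),
                       branches$branch)
  O <- drop(A %*% scores$risk)
  tibble::tibble(
    branch = branches$branch,
    observed = unname(O),
    direction = unname(ifelse(O < 0, "increased", "decreased"))
  )
}

#' Empirical branch p-values against a null row
#'
#' One-sided (default): the fraction of draws at least as extreme as the
#' observed deviation in the observed direction, floored at `1/K` (a
#' deviation never reached in K draws reports `1/K`, not zero).
#'
#' @param observed Numeric vector of observed deviations (one per unit).
#' @param null_values Matrix of null deviations, units x K.
#' @param alternative `"one.sided"` or `"two.sided"`.
#' @return Numeric vector of empirical p-values.
#' @export
branch_empirical_p <- function(observed, null_values,
                               alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  null_values <- rbind(null_values)
  K <- ncol(null_values)
  up <- rowSums(null_values >= observed) / K
  dn <- rowSums(null_values <= observed) / K
  p <- switch(alternative,
    one.sided = ifelse(observed >= 0, up, dn),
    two.sided = pmin(1, 2 * pmin(up, dn))
  )
  unname(pmax(p, 1 / K))
}

# p-value of every null draw against its own row's null distribution,
# under the same sidedness convention as the observed p-values.
null_p_matrix <- function(null_values, alternative = "one.sided") {
  K <- ncol(null_values)
  t(apply(null_values, 1, function(v) {
    sv <- sort(v)
    cnt_lt <- findInterval(v, sv, left.open = TRUE)
    cnt_le <- findInterval(v, sv)
    up <- (K - cnt_lt) / K
    dn <- cnt_le / K
    p <- if (alternative == "one.sided") {
      ifelse(v >= 0, up, dn)
    } else {
      pmin(1, 2 * pmin(up, dn))
    }
    pmax(p, 1 / K)
  }))
}

#' Resampling q-values across correlated branches
#'
#' For an observed branch p-value `a`, `N(a)` is the number of observed
#' branches at significance `<= a` and `E[N(a)]` the mean number of
#' branches reaching `<= a` per null draw (each draw scored against the
#' full null distribution of its own branch). The q-value is
#' `min(1, E[N(a)] / N(a))`: the multiplicity correction across the
#' correlated populations tested.
#'
#' @param p Observed p-values (one per unit).
#' @param null_values Null deviation matrix, units x K.
#' @param alternative Sidedness used for `p`.
#' @return Numeric vector of q-values.
#' @export
branch_qvalues <- function(p, null_values,
                           alternative = c("one.sided", "two.sided")) {
  alternative <- match.arg(alternative)
  null_values <- rbind(null_values)
  K <- ncol(null_values)
  pn <- null_p_matrix(null_values, alternative)
  unname(vapply(p, function(alpha) {
    n_obs <- sum(p <= alpha)
    e_null <- sum(pn <= alpha) / K
    min(1, e_null / n_obs)
  }, numeric(1)))
}

#' Test every tree branch for risk differentiation beyond drift
#'
#' Runs the full branch test: individual risks, observed
#' ancestral-minus-descendant deviations per branch, the matched-SNP
#' resampling null (one shared random panel per draw), empirical
#' p-values and resampling q-values.
#'
#' @param genotypes A [genotype_matrix()].
#' @param tree Rooted population phylogeny whose leaves are the cohort's
#'   populations.
#' @param panel A `disease_panel` (LD-pruned).
#' @param annotations Annotation tibble defining the resampling pool.
#' @param K Number of null draws.
#' @param seed Optional integer seed; fixes the null matrix exactly.
#' @param alternative `"one.sided"` (direction-specific, default) or
#'   `"two.sided"`.
#' @param maf_bin Global-MAF matching bin width.
#' @param keep_null Keep the null matrix on the returned object.
#' @return A `drift_test` object; `tidy()` it for the per-branch table
#'   (`branch`, `descendants`, `n_desc`, `observed`, `direction`, `p`,
#'   `q`).
#' @export
test_differentiation <- function(genotypes, tree, panel, annotations,
                                 K = 2000, seed = NULL,
                                 alternative = c("one.sided", "two.sided"),
                                 maf_bin = 0.02, keep_null = TRUE) {
  alternative <- match.arg(alternative)
  check_tree_populations(tree, genotypes)
  branches <- population_branches(tree)
  scores <- individual_risk(genotypes, panel)
  obs <- observed_branch_deviations(scores, branches)
  A <- contrast_matrix(branches$ancestral, branches$descendants,
                       setNames(scores$population, scores$individual),
                       branches$branch)
  pools <- matched_pools(panel, annotations, maf_bin)
  null <- null_deviations(A, genotypes, panel, pools, K, seed)
  p <- branch_empirical_p(obs$observed, null$values, alternative)
  q <- branch_qvalues(p, null$values, alternative)
  results <- tibble::tibble(
    branch = branches$branch,
    descendants = vapply(branches$descendants, paste, character(1),
                         collapse = ","),
    n_desc = branches$n_desc,
    observed = obs$observed,
    direction = obs$direction,
    p = p,
    q = q
  )
  structure(
    list(results = results, null = if (keep_null) null$values else NULL,
         K = K, seed = seed, mode = "branch", alternative = alternative,
         maf_bin = maf_bin, panel = panel, branches = branches,
         scores = scores, tree = tree),
    class = "drift_test"
  )
}

#' Test one population (or all) against the rest of the world
#'
#' The two-set special case of the branch test: the focal population
#' versus all other populations combined, with the same matched
#' resampling null. With `populations = NULL` every population is tested
#' and the q-value corrects across the populations tested.
#'
#' @inheritParams test_differentiation
#' @param populations Populations to test (default: all).
#' @return A `drift_test` object in population mode; `tidy()` gives
#'   `population`, `risk`, `rest_risk`, `observed` (risk minus rest
#'   risk), `direction`, `p`, `q`.
#' @export
population_vs_rest <- function(genotypes, panel, annotations,
                               K = 2000, seed = NULL, populations = NULL,
                               alternative = c("one.sided", "two.sided"),
                               maf_bin = 0.02, keep_null = TRUE) {
  alternative <- match.arg(alternative)
  all_pops <- unique(genotypes$population)
  populations <- populations %||% all_pops
  unknown <- setdiff(populations, all_pops)
  if (length(unknown) > 0) {
    abort(paste0("unknown population(s): ", paste(unknown, collapse = ", ")))
  }
  small <- table(genotypes$population)[populations] < 2
  if (any(small)) {
    warn(paste0("population(s) with < 2 members: ",
                paste(populations[small], collapse = ", ")))
  }
  scores <- individual_risk(genotypes, panel)
  plus <- lapply(populations, identity)               # focal population
  minus <- lapply(populations, function(p) setdiff(all_pops, p))
  A <- contrast_matrix(plus, minus,
                       setNames(scores$population, scores$individual),
                       populations)
  O <- drop(A %*% scores$risk)
  pools <- matched_pools(panel, annotations, maf_bin)
  null <- null_deviations(A, genotypes, panel, pools, K, seed)
  p <- branch_empirical_p(O, null$values, alternative)
  q <- branch_qvalues(p, null$values, alternative)
  pr <- population_risk(scores)
  risk <- setNames(pr$risk, pr$population)[populations]
  results <- tibble::tibble(
    population = populations,
    risk = unname(risk),
    rest_risk = unname(risk - O),
    observed = unname(O),
    direction = unname(ifelse(O >= 0, "increased", "decreased")),
    p = p,
    q = q
  )
  structure(
    list(results = results, null = if (keep_null) null$values else NULL,
         K = K, seed = seed, mode = "population", alternative = alternative,
         maf_bin = maf_bin, panel = panel, scores = scores),
    class = "drift_test"
  )
}

#' @export
print.drift_test <- function(x, ...) {
  cat(sprintf("<drift_test: %s mode, %d units, K = %d draws>\n",
              x$mode, nrow(x$results), x$K))
  print(x$results, ...)
  invisible(x)
}
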