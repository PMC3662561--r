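# Robustness procedures around the differentiation test: removal of
# individual risk outliers, ascertainment-controlled resampling pools,
# and the per-SNP Fst comparison the set-level test is contrasted with.

#' Remove individual genetic-risk outliers
#'
#' Flags, per population, individuals whose risk score deviates more
#' than `k` times the interquartile range from the population median
#' (default `k = 1.5`), so the differentiation test can be rerun without
#' them.
#'
#' @param scores Individual risks from [individual_risk()].
#' @param k IQR multiplier.
#' @return List with `scores` (the retained rows) and `report` (one row
#'   per population: `population`, `median`, `iqr`, `n_removed`,
#'   `removed` list-column of individual ids).
#' @export
remove_outliers <- function(scores, k = 1.5) {
  small <- scores |>
    dplyr::count(.data$population) |>
    dplyr::filter(.data$n < 4)
  if (nrow(small) > 0) {
    warn(paste0("population(s) with < 4 members; IQR is unstable: ",
                paste(small$population, collapse = ", ")))
  }
  flagged <- scores |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(
      .med = median(.data$risk),
      .iqr = IQR(.data$risk),
      .out = abs(.data$risk - .data$.med) > k * .data$.iqr
    ) |>
    dplyr::ungroup()
  if (any(flagged$.iqr == 0 & flagged$.out)) {
    warn("population with zero IQR: only members equal to the median are kept")
  }
  report <- flagged |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      median = .data$.med[1],
      iqr = .data$.iqr[1],
      n_removed = sum(.data$.out),
      removed = list(.data$individual[.data$.out]),
      .groups = "drop"
    )
  log_counts("remove_outliers", nrow(scores), sum(!flagged$.out),
             what = "individuals")
  list(
    scores = flagged |>
      dplyr::filter(!.data$.out) |>
      dplyr::select(-dplyr::all_of(c(".med", ".iqr", ".out"))),
    report = report
  )
}

#' Subset a genotype matrix to given individuals
#'
#' Companion to [remove_outliers()]: rebuilds the cohort without the
#' flagged individuals so the differentiation test can be rerun.
#'
#' @param genotypes A [genotype_matrix()].
#' @param individuals Individual ids to keep.
#' @return A [genotype_matrix()].
#' @export
subset_individuals <- function(genotypes, individuals) {
  missing <- setdiff(individuals, rownames(genotypes$calls))
  if (length(missing) > 0) {
    abort(paste0("unknown individual(s): ", paste(head(missing, 5), collapse = ", ")))
  }
  genotype_matrix(genotypes$calls[individuals, , drop = FALSE],
                  genotypes$population[individuals],
                  genotypes$counted_allele)
}

#' Restrict the resampling pool to phenotype-associated SNPs
#'
#' Controls for association-ascertainment bias: disease SNPs are
#' enriched in well-tagged regions, so the null is rebuilt by resampling
#' only from SNPs reported associated with any phenotype rather than
#' from all genotyped SNPs.
#'
#' @param annotations Annotation tibble.
#' @return The flagged subset, with retained/discarded counts reported.
#' @export
ascertainment_pool <- function(annotations) {
  out <- dplyr::filter(annotations, .data$phenotype_associated)
  log_counts("ascertainment_pool (phenotype-associated)",
             nrow(annotations), nrow(out))
  if (nrow(out) == 0) abort("no phenotype-associated SNPs in the annotation table")
  out
}

#' Weir-Cockerham Fst per SNP
#'
#' The multi-population Weir-Cockerham (1984) theta estimator, computed
#' per SNP across all populations of the cohort from genotype counts
#' (observed heterozygosity included, sample-size corrected). Negative
#' estimates are kept; SNPs monomorphic across the cohort, or typed in
#' fewer than two populations, get `NA` and are excluded from ranking.
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_ids Optional subset of SNPs (default all).
#' @return Tibble `snp_id`, `fst`, `a`, `b`, `c` (the variance
#'   components; `sum(a) / sum(a + b + c)` is the standard multi-locus
#'   estimate).
#' @export
global_fst <- function(genotypes, snp_ids = NULL) {
  snp_ids <- snp_ids %||% colnames(genotypes$calls)
  calls <- genotypes$calls[, snp_ids, drop = FALSE]
  pops <- unique(genotypes$population)
  per_pop <- lapply(pops, function(pop) {
    m <- calls[genotypes$population == pop, , drop = FALSE]
    n <- colSums(!is.na(m))
    list(n = n,
         p = ifelse(n > 0, colSums(m, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, colSums(m == 1, na.rm = TRUE) / n, NA_real_))
  })
  n_mat <- do.call(rbind, lapply(per_pop, `[[`, "n"))    # pops x snps
  p_mat <- do.call(rbind, lapply(per_pop, `[[`, "p"))
  h_mat <- do.call(rbind, lapply(per_pop, `[[`, "h"))
  typed <- n_mat > 0
  r <- colSums(typed)
  n_tot <- colSums(n_mat)
  nbar <- n_tot / r
  nc <- (n_tot - colSums(n_mat^2) / n_tot) / (r - 1)
  pbar <- colSums(n_mat * ifelse(typed, p_mat, 0)) / n_tot
  s2 <- colSums(n_mat * (ifelse(typed, p_mat, pbar[col(p_mat)]) -
                           rep(pbar, each = nrow(p_mat)))^2 * typed) /
    ((r - 1) * nbar)
  hbar <- colSums(n_mat * ifelse(typed, h_mat, 0)) / n_tot
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  undefined <- r < 2 | pbar <= 0 | pbar >= 1
  fst <- ifelse(undefined, NA_real_, a / (a + b + cc))
  n_undef <- sum(undefined)
  if (n_undef > 0) {
    inform(sprintf("global_fst: %d monomorphic or untestable SNP(s) set to NA",
                   n_undef))
  }
  tibble::tibble(snp_id = snp_ids, fst = unname(fst),
                 a = unname(ifelse(undefined, NA_real_, a)),
                 b = unname(ifelse(undefined, NA_real_, b)),
                 c = unname(ifelse(undefined, NA_real_, cc)))
}

#' Multi-locus Weir-Cockerham Fst
#'
#' Ratio-of-sums combination of the per-SNP variance components:
#' `sum(a) / sum(a + b + c)` over the defined SNPs.
#'
#' @param fst_tbl Output of [global_fst()].
#' @return A single Fst estimate.
#' @export
fst_overall <- function(fst_tbl) {
  ok <- !is.na(fst_tbl$fst)
  sum(fst_tbl$a[ok]) / sum(fst_tbl$a[ok] + fst_tbl$b[ok] + fst_tbl$c[ok])
}

#' Rank-normalised Fst p-values within MAF bins
#'
#' Each focal SNP's Fst is compared to all other SNPs in the same global
#' minor-allele-frequency bin: `rank_p` is the fraction of same-bin pool
#' SNPs with strictly lower Fst (0 for the bin minimum, near 1 for the
#' maximum).
#'
#' @param fst_tbl Per-SNP Fst values ([global_fst()]) covering both the
#'   focal SNPs and the pool.
#' @param snp_ids Focal (panel) SNP ids.
#' @param annotations Annotation tibble supplying `global_maf`.
#' @param maf_bin Bin width (same convention as the differentiation
#'   test).
#' @param min_bin Warn when a bin holds fewer pool SNPs than this.
#' @return Tibble `snp_id`, `fst`, `bin`, `n_bin`, `rank_p`.
#' @export
fst_rank_p <- function(fst_tbl, snp_ids, annotations, maf_bin = 0.02,
                       min_bin = 100) {
  ann <- annotations |>
    dplyr::mutate(bin = maf_bin_index(.data$global_maf, maf_bin)) |>
    dplyr::select("snp_id", "bin")
  tbl <- dplyr::left_join(fst_tbl, ann, by = "snp_id") |>
    dplyr::filter(!is.na(.data$fst))
  focal <- dplyr::filter(tbl, .data$snp_id %in% snp_ids)
  out <- purrr::map_dfr(seq_len(nrow(focal)), function(i) {
    pool <- tbl$fst[tbl$bin == focal$bin[i] & tbl$snp_id != focal$snp_id[i]]
    tibble::tibble(
      snp_id = focal$snp_id[i],
      fst = focal$fst[i],
      bin = focal$bin[i],
      n_bin = length(pool),
      rank_p = if (length(pool) > 0) mean(pool < focal$fst[i]) else NA_real_
    )
  })
  if (any(out$n_bin < min_bin)) {
    warn(sprintf("%d SNP(s) ranked in MAF bins with fewer than %d pool SNPs",
                 sum(out$n_bin < min_bin), min_bin))
  }
  out
}

#' Combine per-SNP rank p-values
#'
#' Converts rank fractions to upper-tail p-values for "more
#' differentiated than expected" (`p = 1 - rank_p`, floored at one over
#' the bin size so the bin maximum does not produce `p = 0`), then
#' combines them with Fisher's method (`X = -2 sum ln p ~ chi-squared
#' with 2k df`) or Stouffer's Z.
#'
#' @param rank_tbl Output of [fst_rank_p()].
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @return The combined p-value.
#' @export
combine_rank_p <- function(rank_tbl, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  ok <- !is.na(rank_tbl$rank_p)
  p <- 1 - rank_tbl$rank_p[ok]
  floor_p <- 1 / pmax(rank_tbl$n_bin[ok], 2)
  p <- pmax(p, floor_p)
  if (length(p) == 0) abort("no defined rank p-values to combine")
  switch(method,
    fisher = pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE),
    stouffer = pnorm(sum(qnorm(p, lower.tail = FALSE)) / sqrt(length(p)),
                     lower.tail = FALSE)
  )
}
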