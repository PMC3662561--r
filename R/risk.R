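# The combined-likelihood-ratio risk model: merge per-study effect sizes
# into per-genotype likelihood ratios L(g), score individuals by the log
# combined likelihood ratio over a disease's SNP panel, and average scores
# into population risks.

#' Filter association records by the study's inclusion rules
#'
#' Keeps SNPs that (a) reach at least one association p-value below
#' `p_max` and (b) were detected in at least `min_populations` distinct
#' study populations. SNPs whose records cannot yield per-genotype
#' likelihood ratios (neither direct LRs nor complete case/control
#' genotype probabilities) are dropped as insufficiently informed.
#'
#' @param records Association tibble (see [read_associations()]).
#' @param p_max Association p-value threshold (default `1e-6`).
#' @param min_populations Minimum number of distinct study populations
#'   (default 2).
#' @return The retained records, with counts reported per filtering step.
#' @export
filter_associations <- function(records, p_max = 1e-6, min_populations = 2) {
  n0 <- dplyr::n_distinct(records$snp_id)
  keep <- records |>
    dplyr::group_by(.data$snp_id, .data$disease) |>
    dplyr::filter(any(.data$p_value < p_max),
                  dplyr::n_distinct(.data$study_population) >= min_populations) |>
    dplyr::ungroup()
  n1 <- dplyr::n_distinct(keep$snp_id)
  log_counts(sprintf("filter_associations (p < %g, >= %d populations)",
                     p_max, min_populations), n0, n1)
  lr <- record_lr(keep)
  ok <- stats::complete.cases(lr)
  # only uninformative records are dropped; a SNP with no informative
  # record left disappears from the panel
  informative <- keep[ok, , drop = FALSE]
  n2 <- dplyr::n_distinct(informative$snp_id)
  if (n2 < n1) log_counts("filter_associations (computable LRs)", n1, n2)
  if (nrow(informative) == 0) inform("filter_associations: no SNPs retained")
  informative
}

# Per-record likelihood ratios for genotypes carrying 0/1/2 risk alleles.
# Uses direct lr_* columns where present, else the ratio of case to
# control genotype probabilities. Returns a data.frame lr0/lr1/lr2 with
# NA where neither is available.
record_lr <- function(records) {
  n <- nrow(records)
  out <- data.frame(lr2 = rep(NA_real_, n), lr1 = NA_real_, lr0 = NA_real_)
  direct <- c("lr_hom_risk", "lr_het", "lr_hom_protective")
  if (all(direct %in% names(records))) {
    out$lr2 <- records$lr_hom_risk
    out$lr1 <- records$lr_het
    out$lr0 <- records$lr_hom_protective
  }
  probs <- c("case_hom_risk", "case_het", "case_hom_protective",
             "control_hom_risk", "control_het", "control_hom_protective")
  if (all(probs %in% names(records))) {
    fill <- is.na(out$lr2) | is.na(out$lr1) | is.na(out$lr0)
    out$lr2[fill] <- records$case_hom_risk[fill] / records$control_hom_risk[fill]
    out$lr1[fill] <- records$case_het[fill] / records$control_het[fill]
    out$lr0[fill] <- records$case_hom_protective[fill] / records$control_hom_protective[fill]
  }
  out
}

#' Combine per-study likelihood ratios across studies
#'
#' For each SNP (and disease), the combined likelihood ratio for genotype
#' `g` is the mean of the per-study ratios weighted by the square root of
#' each study's sample size:
#' `L(g) = sum_i sqrt(A_i) LR_i(g) / sum_i sqrt(A_i)`.
#'
#' @param records Association records (usually after
#'   [filter_associations()]).
#' @return A tibble with one row per SNP/disease: `snp_id`, `disease`,
#'   `risk_allele`, `lr0`, `lr1`, `lr2` (combined L for 0/1/2 copies of
#'   the risk allele) and `n_studies`.
#' @export
combine_likelihood_ratios <- function(records) {
  lr <- record_lr(records)
  bad <- which(!is.na(lr$lr2) & (lr$lr2 <= 0 | lr$lr1 <= 0 | lr$lr0 <= 0))
  if (length(bad) > 0) {
    abort(sprintf("non-positive likelihood ratio in study of SNP %s (%s)",
                  records$snp_id[bad[1]], records$study_population[bad[1]]))
  }
  ok <- stats::complete.cases(lr)
  if (!all(ok)) {
    inform(sprintf("combine_likelihood_ratios: %d record(s) without computable LRs dropped",
                   sum(!ok)))
  }
  dplyr::bind_cols(records, lr)[ok, ] |>
    dplyr::mutate(.w = sqrt(.data$sample_size)) |>
    dplyr::group_by(.data$snp_id, .data$disease) |>
    dplyr::summarise(
      risk_allele = .data$risk_allele[1],
      lr0 = sum(.data$.w * .data$lr0) / sum(.data$.w),
      lr1 = sum(.data$.w * .data$lr1) / sum(.data$.w),
      lr2 = sum(.data$.w * .data$lr2) / sum(.data$.w),
      n_studies = dplyr::n(),
      .groups = "drop"
    )
}

#' Assemble a disease panel
#'
#' Joins combined effects with SNP annotations and the cohort's pooled
#' allele frequencies into the panel object the differentiation test
#' consumes (the disease's SNP vector). `risk_is_minor` records whether
#' each SNP's risk allele is the globally minor allele, which fixes the
#' orientation of matched replacement SNPs in the resampling null.
#'
#' @param combined Output of [combine_likelihood_ratios()], or a tibble
#'   with the same columns.
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param genotypes A [genotype_matrix()] containing the panel SNPs.
#' @param disease Disease to select; default: the only disease present.
#' @return A `disease_panel` tibble: `snp_id`, `risk_allele`,
#'   `risk_is_minor`, `lr0`, `lr1`, `lr2`, `n_studies`, `global_maf`,
#'   `functional_category`.
#' @export
build_panel <- function(combined, annotations, genotypes, disease = NULL) {
  if (is.null(disease)) {
    disease <- unique(combined$disease)
    if (length(disease) != 1) {
      abort("multiple diseases present; pass `disease`")
    }
  }
  panel <- dplyr::filter(combined, .data$disease == !!disease)
  if (anyDuplicated(panel$snp_id)) abort("duplicate SNP ids within panel")
  missing_ann <- setdiff(panel$snp_id, annotations$snp_id)
  if (length(missing_ann) > 0) {
    abort(paste0("panel SNP(s) without annotation: ",
                 paste(head(missing_ann, 5), collapse = ", ")))
  }
  missing_gt <- setdiff(panel$snp_id, colnames(genotypes$calls))
  if (length(missing_gt) > 0) {
    abort(paste0("panel SNP(s) not genotyped: ",
                 paste(head(missing_gt, 5), collapse = ", ")))
  }
  f_counted <- pooled_frequency(genotypes)[panel$snp_id]
  counted <- genotypes$counted_allele[panel$snp_id]
  f_risk <- ifelse(panel$risk_allele == counted, f_counted, 1 - f_counted)
  panel <- panel |>
    dplyr::mutate(risk_is_minor = f_risk <= 0.5) |>
    dplyr::left_join(
      dplyr::select(annotations, "snp_id", "global_maf", "functional_category"),
      by = "snp_id"
    ) |>
    dplyr::select("snp_id", "risk_allele", "risk_is_minor", "lr0", "lr1",
                  "lr2", "n_studies", "global_maf", "functional_category")
  structure(panel, disease = disease,
            class = c("disease_panel", class(panel)))
}

#' Restrict association records to a group of study populations
#'
#' Recomputing effect sizes from, say, Asian-based studies only requires
#' dropping every record whose study population is outside the group and
#' re-running [combine_likelihood_ratios()]. Panel SNPs left with no
#' records simply disappear, so the restricted panel may be smaller.
#'
#' @param records Association records.
#' @param population_group Character vector of study-population labels to
#'   keep.
#' @return The surviving records.
#' @export
restrict_to_study_populations <- function(records, population_group) {
  n0 <- dplyr::n_distinct(records$snp_id)
  out <- dplyr::filter(records, .data$study_population %in% population_group)
  n1 <- dplyr::n_distinct(out$snp_id)
  log_counts("restrict_to_study_populations", n0, n1)
  out
}

#' Greedy LD pruning of a panel
#'
#' Iterates panel SNPs in order and drops any SNP whose squared genotype
#' dosage correlation with an already kept SNP reaches `r2_threshold`.
#' r-squared is computed on the pooled cohort by default, or within one
#' reference population. Monomorphic SNPs (undefined r-squared) are kept.
#'
#' @param panel A `disease_panel`.
#' @param genotypes A [genotype_matrix()].
#' @param r2_threshold Exclusion threshold (default 0.2).
#' @param population Optional single population to compute r-squared in.
#' @return The pruned panel (same class, attributes kept).
#' @export
ld_prune <- function(panel, genotypes, r2_threshold = 0.2, population = NULL) {
  calls <- genotypes$calls[, panel$snp_id, drop = FALSE]
  if (!is.null(population)) {
    calls <- calls[genotypes$population == population, , drop = FALSE]
  }
  sds <- apply(calls, 2, stats::sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  if (any(mono)) {
    inform(sprintf("ld_prune: %d monomorphic SNP(s) kept (r-squared undefined)",
                   sum(mono)))
  }
  kept <- integer(0)
  for (j in seq_len(ncol(calls))) {
    if (mono[j]) {
      kept <- c(kept, j)
      next
    }
    informative_kept <- kept[!mono[kept]]
    drop <- FALSE
    for (k in informative_kept) {
      r <- suppressWarnings(
        stats::cor(calls[, j], calls[, k], use = "pairwise.complete.obs")
      )
      if (!is.na(r) && r^2 >= r2_threshold) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, j)
  }
  log_counts(sprintf("ld_prune (r2 >= %g)", r2_threshold),
             nrow(panel), length(kept))
  out <- panel[kept, , drop = FALSE]
  structure(out, disease = attr(panel, "disease"),
            class = class(panel))
}

#' Individual genetic risk scores
#'
#' The risk score of a person is the log of the product of combined
#' likelihood ratios over the disease's SNPs, i.e. the sum of
#' `ln L(g)` over panel SNPs with a called genotype. Missing genotypes
#' contribute nothing (absent evidence, factor 1); natural logarithm.
#'
#' @param genotypes A [genotype_matrix()].
#' @param panel A `disease_panel` (LD-pruned).
#' @return A tibble with one row per individual: `individual`,
#'   `population`, `risk`, `n_snps_used`.
#' @export
individual_risk <- function(genotypes, panel) {
  lnl <- panel_logl(genotypes, panel)     # individuals x SNPs, NA = missing
  all_missing <- rowSums(!is.na(lnl)) == 0
  if (any(all_missing) && ncol(lnl) > 0) {
    warn(sprintf("%d individual(s) with all panel genotypes missing; risk set to 0",
                 sum(all_missing)))
  }
  tibble::tibble(
    individual = rownames(genotypes$calls),
    population = unname(genotypes$population),
    risk = unname(rowSums(lnl, na.rm = TRUE)),
    n_snps_used = as.integer(unname(rowSums(!is.na(lnl))))
  )
}

# Matrix of per-SNP log combined likelihood ratios for each individual;
# NA where the genotype is missing.
panel_logl <- function(genotypes, panel) {
  calls <- genotypes$calls[, panel$snp_id, drop = FALSE]
  counted <- genotypes$counted_allele[panel$snp_id]
  # risk-allele copy count: flip when the risk allele is not the counted one
  flip <- panel$risk_allele != counted
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  }
  lnl_tab <- rbind(log(panel$lr0), log(panel$lr1), log(panel$lr2)) # 3 x SNPs
  out <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (g in 0:2) {
    idx <- which(calls == g)
    if (length(idx) > 0) {
      cols <- (idx - 1) %/% nrow(calls) + 1
      out[idx] <- lnl_tab[g + 1, cols]
    }
  }
  out
}

#' Population genetic risk
#'
#' A population's genetic risk is the arithmetic mean of its members'
#' risk scores.
#'
#' @param scores Individual scores from [individual_risk()].
#' @return A tibble `population`, `risk`, `n_members`.
#' @export
population_risk <- function(scores) {
  if (nrow(scores) == 0) abort("no individuals: cannot compute population risk")
  scores |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(risk = mean(.data$risk), n_members = dplyr::n(),
                     .groups = "drop")
}

#' Risk difference between two populations
#'
#' `D_AB = R_A - R_B`: positive when population A's genetic risk is the
#' higher one. Antisymmetric by construction.
#'
#' @param population_risks Output of [population_risk()].
#' @param pop_a,pop_b Population labels.
#' @return A one-row tibble `pop_a`, `pop_b`, `difference`.
#' @export
risk_difference <- function(population_risks, pop_a, pop_b) {
  r <- setNames(population_risks$risk, population_risks$population)
  for (p in c(pop_a, pop_b)) {
    if (!p %in% names(r)) abort(paste0("unknown population: ", p))
  }
  tibble::tibble(pop_a = pop_a, pop_b = pop_b,
                 difference = unname(r[pop_a] - r[pop_b]))
}
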