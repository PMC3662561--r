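# Outlier removal, ascertainment-controlled pools and Fst comparisons.

test_that("outlier removal follows the 1.5-IQR-from-median rule", {
  scores <- tibble::tibble(
    individual = sprintf("i%d", 1:5),
    population = "P", risk = c(1, 2, 3, 4, 5), n_snps_used = 1L
  )
  out <- suppressMessages(suppressWarnings(remove_outliers(scores)))
  # median 3, IQR 2: the largest deviation (2) is under 3, nothing removed
  expect_equal(nrow(out$scores), 5L)
  expect_equal(out$report$n_removed, 0L)

  extreme <- dplyr::mutate(scores, risk = c(1, 2, 3, 4, 50))
  out2 <- suppressMessages(suppressWarnings(remove_outliers(extreme)))
  expect_equal(out2$report$removed[[1]], "i5")
  expect_equal(nrow(out2$scores), 4L)
  expect_equal(out2$report$median, 3)
  expect_equal(out2$report$iqr, 2)

  flat <- dplyr::mutate(scores, risk = 0.4)
  out3 <- suppressMessages(suppressWarnings(remove_outliers(flat)))
  expect_equal(out3$report$n_removed, 0L)
})

test_that("outlier removal never strips more than half a unimodal population", {
  co <- toy_cohort(n_per_pop = 20)
  scores <- individual_risk(co$genotypes, co$panel)
  out <- suppressMessages(remove_outliers(scores))
  frac <- out$report$n_removed / 20
  expect_true(all(frac <= 0.5))
})

test_that("significance survives outlier removal with a planted outlier", {
  co <- toy_cohort(seed = 612, n_pool_snps = 800, panel_snps = 10,
                   n_per_pop = 25, event = list(branch = "Pop03", delta = 0.15))
  scores <- individual_risk(co$genotypes, co$panel)
  # plant one outlier: +3 SD risk in an unaffected population
  boost <- 3 * stats::sd(scores$risk)
  scores_out <- dplyr::mutate(
    scores, risk = risk + (individual == "Pop01_001") * boost
  )
  flagged <- suppressMessages(suppressWarnings(remove_outliers(scores_out)))
  expect_true("Pop01_001" %in% unlist(flagged$report$removed))
  g2 <- subset_individuals(co$genotypes, flagged$scores$individual)
  pvr <- population_vs_rest(g2, co$panel, co$annotations, K = 1000, seed = 8,
                            populations = "Pop03")
  expect_lt(tidy(pvr)$p, 0.05)
})

test_that("the ascertainment pool keeps flagged SNPs and preserves results when all are flagged", {
  co <- toy_cohort()
  ann_all <- dplyr::mutate(co$annotations, phenotype_associated = TRUE)
  expect_identical(suppressMessages(ascertainment_pool(ann_all)), ann_all)
  t_full <- test_differentiation(co$genotypes, co$tree, co$panel, ann_all,
                                 K = 300, seed = 21)
  t_restricted <- test_differentiation(
    co$genotypes, co$tree, co$panel,
    suppressMessages(ascertainment_pool(ann_all)), K = 300, seed = 21
  )
  expect_identical(t_full$results, t_restricted$results)

  none <- dplyr::mutate(co$annotations, phenotype_associated = FALSE)
  expect_error(suppressMessages(ascertainment_pool(none)),
               "no phenotype-associated")
})

test_that("an injected event stays significant under the restricted pool", {
  co <- toy_cohort(seed = 733, n_pool_snps = 1500, panel_snps = 10,
                   n_per_pop = 25, phenotype_fraction = 0.5,
                   event = list(branch = "Pop01", delta = 0.15))
  restricted <- suppressMessages(ascertainment_pool(co$annotations))
  pvr <- population_vs_rest(co$genotypes, co$panel, restricted,
                            K = 1000, seed = 4, populations = "Pop01")
  expect_lt(tidy(pvr)$p, 0.05)
  expect_equal(tidy(pvr)$direction, "increased")
})

test_that("Weir-Cockerham theta matches the hand-computed two-population toy", {
  # pop1: 8 hom-risk, 2 het (p = 0.9, h = 0.2); pop2: 2/6/2 (p = 0.5, h = 0.6)
  calls <- cbind(s1 = c(rep(2L, 8), rep(1L, 2), rep(2L, 2), rep(1L, 6),
                        rep(0L, 2)))
  rownames(calls) <- sprintf("i%02d", 1:20)
  g <- genotype_matrix(calls, setNames(rep(c("P1", "P2"), each = 10),
                                       rownames(calls)))
  fst <- global_fst(g)
  # hand evaluation: a = 0.08 - 0.07/9, b = (10/9)(-0.02), c = 0.2,
  # theta = a / (a + b + c) = 0.2888889
  expect_equal(fst$fst, 0.2888889, tolerance = 1e-6)
  expect_equal(fst$a, 0.08 - 0.07 / 9, tolerance = 1e-10)
  expect_equal(fst$b, -0.2 / 9, tolerance = 1e-10)
  expect_equal(fst$c, 0.2, tolerance = 1e-10)
})

test_that("theta behaves at the fixation extremes", {
  # identical frequencies in both populations: theta ~ 0 (possibly negative)
  withr::with_seed(14, {
    calls <- cbind(s1 = rbinom(40, 2, 0.4))
  })
  rownames(calls) <- sprintf("i%02d", 1:40)
  g <- genotype_matrix(calls, setNames(rep(c("P1", "P2"), each = 20),
                                       rownames(calls)))
  expect_lt(abs(global_fst(g)$fst), 0.15)

  # opposite fixation: theta = 1
  calls2 <- cbind(s1 = c(rep(2L, 10), rep(0L, 10)))
  rownames(calls2) <- sprintf("i%02d", 1:20)
  g2 <- genotype_matrix(calls2, setNames(rep(c("P1", "P2"), each = 10),
                                         rownames(calls2)))
  expect_equal(global_fst(g2)$fst, 1)

  # monomorphic SNP is undefined and excluded from ranking
  calls3 <- cbind(s1 = rep(2L, 20), s2 = c(rep(2L, 10), rep(0L, 10)))
  rownames(calls3) <- sprintf("i%02d", 1:20)
  g3 <- genotype_matrix(calls3, setNames(rep(c("P1", "P2"), each = 10),
                                         rownames(calls3)))
  fst3 <- suppressMessages(global_fst(g3))
  expect_true(is.na(fst3$fst[1]))
  expect_false(is.na(fst3$fst[2]))
})

test_that("multi-locus theta recovers the simulated drift parameter", {
  star <- ape::stree(8, "star")
  star$tip.label <- sprintf("Pop%02d", 1:8)
  fr <- simulate_frequencies(star, 1500, drift_f = 0.05, seed = 81)
  g <- simulate_genotypes(fr, n_per_pop = 30, seed = 82)
  fst <- suppressMessages(global_fst(g))
  expect_equal(fst_overall(fst), 0.05, tolerance = 0.1)
})

test_that("rank p-values are bin-restricted fractions of lower Fst", {
  co <- toy_cohort(n_pool_snps = 900)
  fst <- suppressMessages(global_fst(co$genotypes))
  ranks <- suppressWarnings(
    fst_rank_p(fst, co$panel$snp_id, co$annotations, maf_bin = 0.1)
  )
  expect_true(all(ranks$rank_p >= 0 & ranks$rank_p <= 1, na.rm = TRUE))
  # spot-check one SNP against direct enumeration
  i <- which.max(ranks$n_bin)
  ann_bin <- floor(pmin(co$annotations$global_maf / 0.1, 4.999))
  bin_snps <- co$annotations$snp_id[ann_bin == ranks$bin[i]]
  pool_fst <- fst$fst[match(setdiff(bin_snps, ranks$snp_id[i]), fst$snp_id)]
  pool_fst <- pool_fst[!is.na(pool_fst)]
  expect_equal(ranks$rank_p[i], mean(pool_fst < ranks$fst[i]))
  # extremes: bin minimum gets 0, bin maximum gets ~1
  lowest <- fst$snp_id[which.min(fst$fst)]
  r_low <- suppressWarnings(fst_rank_p(fst, lowest, co$annotations,
                                       maf_bin = 0.5))
  expect_equal(r_low$rank_p, 0)
})

test_that("Fisher combination of rank p-values matches hand arithmetic", {
  tbl <- tibble::tibble(snp_id = "a", fst = 0.1, bin = 1, n_bin = 1000,
                        rank_p = 0.5)
  expect_equal(combine_rank_p(tbl), 1 - 0.5)   # k = 1 identity
  two <- tibble::tibble(snp_id = c("a", "b"), fst = 0.1, bin = 1,
                        n_bin = 1000, rank_p = c(0.5, 0.5))
  # X = -2(ln .5 + ln .5) = 2.7726 on 4 df
  expect_equal(combine_rank_p(two), 0.5965736, tolerance = 1e-6)
  ones <- dplyr::mutate(two, rank_p = 0)        # upper p = 1 for both
  expect_equal(combine_rank_p(ones), 1)
  # rank_p = 1 is floored at 1/bin size instead of collapsing to p = 0
  capped <- dplyr::mutate(two, rank_p = 1)
  expect_gt(combine_rank_p(capped), 0)
  expect_lt(combine_rank_p(capped), 1e-4)
  # stouffer variant stays in range
  expect_lt(combine_rank_p(two, method = "stouffer"), 1)
})

test_that("the set-level test sees correlated shifts that per-SNP Fst ranking misses", {
  # a correlated shift in one of eight populations: a set-level signal,
  # but a per-SNP Fst perturbation too small to stand out within MAF bins
  co <- suppressMessages(suppressWarnings(simulate_cohort(
    n_populations = 8, n_per_pop = 25, n_pool_snps = 1600, drift_f = 0.05,
    panel_snps = 12, phenotype_fraction = 0.4, seed = 915,
    event = list(branch = "Pop04", delta = 0.12)
  )))
  tst <- population_vs_rest(co$genotypes, co$panel, co$annotations,
                            K = 2000, seed = 6)
  expect_lt(min(tidy(tst)$q), 0.05)
  fst <- suppressMessages(global_fst(co$genotypes))
  ranks <- suppressWarnings(fst_rank_p(fst, co$panel$snp_id, co$annotations,
                                       maf_bin = 0.05))
  expect_gt(combine_rank_p(ranks), 0.05)
})
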