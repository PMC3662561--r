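# The matched-SNP resampling null and branch differentiation test.

test_that("observed deviations are ancestral-minus-descendant means", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  scores <- tibble::tibble(
    individual = sprintf("i%d", 1:4),
    population = c("A", "A", "B", "B"),
    risk = c(1, 1, 0, 0), n_snps_used = 1L
  )
  br <- population_branches(tree)
  obs <- observed_branch_deviations(scores, br)
  # the tested branch partitions A (ancestral) from B (descendant): O = 1
  expect_equal(nrow(obs), 1L)
  expect_equal(abs(obs$observed), 1)

  flat <- dplyr::mutate(scores, risk = 0.7)
  expect_true(all(observed_branch_deviations(flat, br)$observed == 0))
})

test_that("a 4-leaf hand fixture reproduces hand-computed contrasts", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # 12 individuals, 3 per population, hand-set risks
  risks <- list(A = c(1, 2, 3), B = c(0, 0, 3), C = c(-1, 0, 1), D = c(2, 2, 2))
  scores <- tibble::tibble(
    individual = sprintf("i%02d", 1:12),
    population = rep(names(risks), each = 3),
    risk = unlist(risks), n_snps_used = 1L
  )
  br <- population_branches(tree)
  obs <- observed_branch_deviations(scores, br)
  o <- setNames(obs$observed, obs$branch)
  # branch above {A,B}: mean(C,D) - mean(A,B) = 1 - 1.5
  expect_equal(unname(o[br$branch[br$n_desc == 2]][1]), 1 - 1.5)
  # leaf branch A: mean(B,C,D) - mean(A) = 1 - 2
  expect_equal(unname(o["A"]), 1 - 2)
  expect_equal(unname(o["D"]), (6 + 3 + 0) / 9 - 2)
  expect_equal(obs$direction[match("D", obs$branch)], "increased")
})

test_that("matched pools share MAF bin and category and exclude the SNP itself", {
  co <- toy_cohort()
  pools <- matched_pools(co$panel, co$annotations, maf_bin = 0.02)
  ann <- co$annotations
  for (i in seq_len(nrow(co$panel))) {
    snp <- co$panel$snp_id[i]
    cand <- pools[[snp]]
    expect_false(snp %in% cand)
    idx <- match(cand, ann$snp_id)
    expect_true(all(ann$functional_category[idx] ==
                      co$panel$functional_category[i]))
    expect_true(all(floor(ann$global_maf[idx] / 0.02) ==
                      floor(co$panel$global_maf[i] / 0.02) |
                      ann$global_maf[idx] == 0.5))
    # brute-force enumeration over the annotation table agrees
    brute <- ann$snp_id[
      pmin(floor(ann$global_maf / 0.02), 24) ==
        pmin(floor(co$panel$global_maf[i] / 0.02), 24) &
        ann$functional_category == co$panel$functional_category[i] &
        ann$snp_id != snp
    ]
    expect_setequal(cand, brute)
  }
  stripped <- dplyr::filter(ann, functional_category !=
                              co$panel$functional_category[1])
  expect_error(matched_pools(co$panel, stripped), "empty matched pool")
})

test_that("null panel draws are deterministic under a seed and uniform over pools", {
  co <- toy_cohort()
  pools <- matched_pools(co$panel, co$annotations)
  a <- draw_null_panel(co$panel, pools, seed = 5)
  b <- draw_null_panel(co$panel, pools, seed = 5)
  expect_identical(a$replacement_snp, b$replacement_snp)

  # a singleton pool forces a deterministic replacement
  one <- lapply(pools, function(p) p[1])
  expect_equal(draw_null_panel(co$panel, one, seed = 1)$replacement_snp,
               unname(vapply(one, identity, character(1))))

  # uniformity: each candidate drawn with frequency ~ 1 / pool size
  snp <- co$panel$snp_id[1]
  pool1 <- pools[[snp]]
  nm <- build_null_matrix(co$genotypes, co$tree, co$panel, co$annotations,
                          K = 10000, seed = 11, keep_draws = TRUE)
  freq <- table(factor(nm$draws[, snp], levels = pool1)) / 10000
  expect_true(all(abs(freq - 1 / length(pool1)) <
                    3 * sqrt((1 / length(pool1)) / 10000) + 1e-3))
})

test_that("the null engine matches a from-scratch recomputation of stored draws", {
  co <- toy_cohort(panel_snps = 5)
  nm <- build_null_matrix(co$genotypes, co$tree, co$panel, co$annotations,
                          K = 50, seed = 23, keep_draws = TRUE)
  br <- population_branches(co$tree)
  redone <- vapply(seq_len(50), function(k) {
    recompute_draw_deviation(co$genotypes, co$panel, nm$draws[k, ],
                             br$ancestral, br$descendants)
  }, numeric(nrow(br)))
  expect_equal(unname(nm$values), unname(redone), tolerance = 1e-10)

  # empirical p equals a literal count over the recomputed draws
  scores <- individual_risk(co$genotypes, co$panel)
  obs <- observed_branch_deviations(scores, br)
  p <- branch_empirical_p(obs$observed, nm$values)
  literal <- vapply(seq_len(nrow(br)), function(i) {
    if (obs$observed[i] >= 0) max(mean(redone[i, ] >= obs$observed[i]), 1 / 50)
    else max(mean(redone[i, ] <= obs$observed[i]), 1 / 50)
  }, numeric(1))
  expect_equal(p, literal)
})

test_that("shared draws preserve correlation between related branches", {
  co <- toy_cohort(panel_snps = 10)
  nm <- build_null_matrix(co$genotypes, co$tree, co$panel, co$annotations,
                          K = 400, seed = 31)
  br <- population_branches(co$tree)
  # a parent branch and a child below it share most of their contrast,
  # so their null rows are positively correlated under shared draws
  sets <- br$descendants
  pair <- NULL
  for (i in which(!br$is_leaf)) {
    kids <- which(br$branch != br$branch[i] &
                    vapply(sets, function(s) all(s %in% sets[[i]]), logical(1)))
    if (length(kids) >= 1) pair <- c(i, kids[1])
  }
  skip_if(is.null(pair), "no nested branch pair in this topology")
  expect_gt(cor(nm$values[pair[1], ], nm$values[pair[2], ]), 0)
  # and the correlation matches a from-scratch recomputation of the draws
  nm2 <- build_null_matrix(co$genotypes, co$tree, co$panel, co$annotations,
                           K = 60, seed = 31, keep_draws = TRUE)
  redone <- vapply(seq_len(60), function(k) {
    recompute_draw_deviation(co$genotypes, co$panel, nm2$draws[k, ],
                             br$ancestral, br$descendants)
  }, numeric(nrow(br)))
  expect_equal(cor(nm2$values[pair[1], ], nm2$values[pair[2], ]),
               cor(redone[pair[1], ], redone[pair[2], ]), tolerance = 1e-10)
})

test_that("empirical p follows the direction-specific counting convention", {
  # a null row where exactly 15 of 100,000 draws exceed the observed value
  null_row <- matrix(seq_len(100000) / 100000, nrow = 1)
  obs <- 1 - 14.5 / 100000
  expect_equal(branch_empirical_p(obs, null_row), 1.5e-4)
  # nothing more extreme: the floor 1/K, never zero
  expect_equal(branch_empirical_p(2, null_row), 1e-5)
  # a central observation sits near p = 0.5
  expect_equal(branch_empirical_p(0.5, null_row), 0.50001, tolerance = 1e-3)
  # column order is irrelevant (exchangeability)
  shuffled <- null_row[, withr::with_seed(2, sample(100000)), drop = FALSE]
  expect_equal(branch_empirical_p(obs, shuffled), 1.5e-4)
})

test_that("q-values match brute-force enumeration of the null matrix", {
  withr::with_seed(9, {
    null_row <- matrix(rnorm(100), nrow = 1)
  })
  obs <- unname(quantile(null_row, 0.97))
  p <- branch_empirical_p(obs, null_row)
  q <- branch_qvalues(p, null_row)
  # brute force E[N(alpha)]: score every draw against the full row
  null_p <- vapply(null_row[1, ], function(v) {
    if (v >= 0) max(mean(null_row >= v), 1 / 100)
    else max(mean(null_row <= v), 1 / 100)
  }, numeric(1))
  expect_equal(q, min(1, mean(null_p <= p) / 1))

  # all-observed p = 1 caps q at 1
  many <- matrix(rnorm(300), nrow = 3)
  expect_equal(branch_qvalues(rep(1, 3), many), rep(1, 3))
})

test_that("the full branch test is deterministic and honours its floor", {
  co <- toy_cohort()
  t1 <- test_differentiation(co$genotypes, co$tree, co$panel, co$annotations,
                             K = 500, seed = 99)
  t2 <- test_differentiation(co$genotypes, co$tree, co$panel, co$annotations,
                             K = 500, seed = 99)
  expect_identical(t1$results, t2$results)
  expect_identical(t1$null, t2$null)
  expect_true(all(t1$results$p >= 1 / 500))
  expect_true(all(t1$results$q >= 0 & t1$results$q <= 1))
  expect_s3_class(tidy(t1), "tbl_df")
  expect_equal(glance(t1)$K, 500)
})

test_that("population-vs-rest flags an injected leaf event with direction", {
  co <- toy_cohort(seed = 407, n_pool_snps = 800, panel_snps = 10,
                   n_per_pop = 25,
                   event = list(branch = "Pop02", delta = 0.15))
  pvr <- population_vs_rest(co$genotypes, co$panel, co$annotations,
                            K = 1000, seed = 3)
  res <- tidy(pvr)
  hit <- res[res$population == "Pop02", ]
  expect_lt(hit$p, 0.05)
  expect_equal(hit$direction, "increased")
  expect_equal(hit$risk - hit$rest_risk, hit$observed)
  # the other populations are not systematically extreme
  expect_gt(min(res$p[res$population != "Pop02"]), 1 / 1000)
})

test_that("a population drawn from the rest's distribution is central", {
  co <- toy_cohort(n_per_pop = 16)
  g <- co$genotypes
  # split one population in two: the split-off half is genetically
  # identical in distribution to its source, so its vs-rest deviation
  # is pure sampling noise
  pops <- g$population
  half <- names(pops)[pops == "Pop01"][1:8]
  pops[half] <- "Pop01b"
  g2 <- genotype_matrix(g$calls, pops, g$counted_allele)
  pvr <- population_vs_rest(g2, co$panel, co$annotations, K = 500, seed = 13,
                            populations = "Pop01b")
  expect_lt(abs(tidy(pvr)$observed), 0.5)
  expect_gt(tidy(pvr)$p, 0.05)
})
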