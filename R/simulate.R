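# Synthetic cohorts with known truth. Populations are related by a tree;
# allele frequencies drift from shared ancestral frequencies along each
# branch under the Balding-Nichols model (Beta with the parent's mean and
# variance F p (1 - p)); genotypes are Hardy-Weinberg within populations;
# a genome-wide pool of annotated neutral SNPs feeds the matched
# resampling null; disease panels carry per-genotype likelihood ratios
# from synthetic association studies; and a risk-allele frequency shift
# can be injected on a chosen branch to create a differentiation event
# with a recorded truth table.

#' Simulate a random rooted population tree
#'
#' Simulated trees are coalescent ([ape::rcoal]), hence ultrametric: every
#' population sits at the same total divergence from the shared ancestor,
#' which makes the drift parameterisation of [simulate_frequencies()]
#' exact for all leaves.
#'
#' @param n_populations Number of leaf populations.
#' @param seed Optional integer seed.
#' @param labels Optional leaf labels (default `Pop01`, `Pop02`, ...).
#' @return A rooted binary ultrametric [ape::phylo].
#' @export
simulate_population_tree <- function(n_populations, seed = NULL, labels = NULL) {
  labels <- labels %||% sprintf("Pop%02d", seq_len(n_populations))
  with_seed_or_not(seed, ape::rcoal(n_populations, tip.label = labels))
}

#' Simulate allele frequencies drifting along a tree
#'
#' Starting from ancestral frequencies at the root (uniform on
#' `[0.05, 0.95]` by default, avoiding boundary fixation), each child
#' node's frequency is drawn from a Beta distribution with mean equal to
#' the parent frequency `p` and variance `f_e p (1 - p)`
#' (Balding-Nichols), where `f_e` is the edge's share of the total drift:
#' `f_e = 1 - (1 - F)^(t_e / T)` for an edge of length `t_e` on a tree of
#' depth `T`. Balding-Nichols variances compose multiplicatively in
#' `1 - f`, so on an ultrametric tree every population ends at total
#' divergence exactly `F p (1 - p)` from the ancestor — `drift_f` is the
#' leaf-level fixation index (the Fst the pool SNPs should show), while
#' the tree shape sets the correlation between populations. Trees without
#' branch lengths get unit lengths (a star tree then reduces to one
#' Balding-Nichols step of size `F` per population). `F = 0` copies the
#' parent exactly; frequencies of 0 or 1 stay fixed (no drift possible).
#'
#' @param tree A rooted [ape::phylo], ideally ultrametric (see
#'   [simulate_population_tree()]).
#' @param n_snps Number of SNPs.
#' @param drift_f Total ancestor-to-population drift `F` in `[0, 1)`.
#' @param ancestral_freq Optional vector of ancestral frequencies in
#'   `[0, 1]` (length `n_snps`).
#' @param seed Optional integer seed.
#' @return A tibble `population`, `snp_id`, `freq` (frequency of allele
#'   `"A"`, the counted allele) with the ancestral frequencies attached
#'   as attribute `"ancestral"`.
#' @export
simulate_frequencies <- function(tree, n_snps, drift_f,
                                 ancestral_freq = NULL, seed = NULL) {
  if (drift_f < 0 || drift_f >= 1) abort("drift_f must be in [0, 1)")
  snp_ids <- sprintf("snp%05d", seq_len(n_snps))
  with_seed_or_not(seed, {
    p0 <- ancestral_freq %||% runif(n_snps, 0.05, 0.95)
    if (length(p0) != n_snps) abort("ancestral_freq must have length n_snps")
    if (any(p0 < 0 | p0 > 1)) abort("ancestral frequencies must be in [0, 1]")
    n_tip <- length(tree$tip.label)
    node_freq <- matrix(NA_real_, nrow = n_tip + tree$Nnode, ncol = n_snps)
    node_freq[n_tip + 1L, ] <- p0
    ord <- ape::reorder.phylo(tree, "cladewise")
    edge <- ord$edge
    len <- ord$edge.length %||% rep(1, nrow(edge))
    ord$edge.length <- len
    depth <- max(ape::node.depth.edgelength(ord))
    f_edge <- 1 - (1 - drift_f)^(len / depth)
    for (i in seq_len(nrow(edge))) {
      node_freq[edge[i, 2], ] <-
        drift_child_freq(node_freq[edge[i, 1], ], f_edge[i])
    }
    leaf <- node_freq[seq_len(n_tip), , drop = FALSE]
    out <- tibble::tibble(
      population = rep(tree$tip.label, times = n_snps),
      snp_id = rep(snp_ids, each = n_tip),
      freq = as.vector(leaf)
    )
    attr(out, "ancestral") <- setNames(p0, snp_ids)
    out
  })
}

# One Balding-Nichols step: child frequencies given parent frequencies p
# and drift coefficient F. Mean p, variance F p (1 - p).
drift_child_freq <- function(p, f) {
  if (f == 0) return(p)
  out <- p
  inner <- p > 0 & p < 1
  shape <- (1 - f) / f
  out[inner] <- rbeta(sum(inner), p[inner] * shape, (1 - p[inner]) * shape)
  out
}

#' Simulate Hardy-Weinberg genotypes from population frequencies
#'
#' Within each population, the genotype at each SNP is
#' `Binomial(2, freq)` copies of allele `"A"`; an optional missingness
#' rate masks calls at random.
#'
#' @param freqs Frequency tibble from [simulate_frequencies()].
#' @param n_per_pop Individuals per population (single value or named by
#'   population).
#' @param missing_rate Probability a call is missing (default 0).
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(freqs, n_per_pop, missing_rate = 0, seed = NULL) {
  pops <- unique(freqs$population)
  snps <- unique(freqs$snp_id)
  if (length(n_per_pop) == 1) {
    n_per_pop <- setNames(rep(n_per_pop, length(pops)), pops)
  }
  if (any(n_per_pop < 1)) abort("n_per_pop must be >= 1")
  fmat <- matrix(freqs$freq, nrow = length(pops), ncol = length(snps),
                 dimnames = list(pops, snps))
  # simulate_frequencies emits population-major order; rebuild defensively
  fmat[cbind(match(freqs$population, pops), match(freqs$snp_id, snps))] <-
    freqs$freq
  with_seed_or_not(seed, {
    calls_by_pop <- lapply(pops, function(pop) {
      n <- n_per_pop[[pop]]
      matrix(rbinom(n * length(snps), size = 2,
                    prob = rep(fmat[pop, ], each = n)),
             nrow = n, ncol = length(snps))
    })
    calls <- do.call(rbind, calls_by_pop)
    if (missing_rate > 0) {
      calls[runif(length(calls)) < missing_rate] <- NA_integer_
    }
    ids <- unlist(lapply(pops, function(pop) {
      sprintf("%s_%03d", pop, seq_len(n_per_pop[[pop]]))
    }))
    dimnames(calls) <- list(ids, snps)
    population <- setNames(rep(pops, times = n_per_pop[pops]), ids)
    genotype_matrix(calls, population)
  })
}

#' Annotate a simulated SNP pool
#'
#' Computes each SNP's realised global (pooled-cohort) minor allele
#' frequency and assigns a functional category and a
#' phenotype-association flag. Category weights default to a
#' genome-like mix dominated by intronic and unannotated SNPs; the
#' phenotype-associated fraction defaults to 0.07, matching the
#' genome-wide ratio of reported-association SNPs to genotyped SNPs.
#'
#' @param genotypes A [genotype_matrix()].
#' @param category_weights Named numeric vector over the eight
#'   functional categories.
#' @param phenotype_fraction Probability a SNP is flagged
#'   phenotype-associated.
#' @param seed Optional integer seed.
#' @return Annotation tibble: `snp_id`, `global_maf`,
#'   `functional_category`, `phenotype_associated`.
#' @export
simulate_annotations <- function(genotypes,
                                 category_weights = NULL,
                                 phenotype_fraction = 0.07,
                                 seed = NULL) {
  category_weights <- category_weights %||% c(
    "frameshift" = 0.01, "nonsense" = 0.01, "missense" = 0.05,
    "untranslated" = 0.04, "near-gene" = 0.10, "intron" = 0.45,
    "coding-synonymous" = 0.04, "unknown" = 0.30
  )
  bad <- setdiff(names(category_weights), functional_categories())
  if (length(bad) > 0) abort(paste0("unknown category: ", paste(bad, collapse = ", ")))
  f <- pooled_frequency(genotypes)
  with_seed_or_not(seed, tibble::tibble(
    snp_id = colnames(genotypes$calls),
    global_maf = pmin(f, 1 - f),
    functional_category = sample(names(category_weights), length(f),
                                 replace = TRUE, prob = category_weights),
    phenotype_associated = runif(length(f)) < phenotype_fraction
  ))
}

#' Generate a synthetic disease panel with association records
#'
#' Draws panel SNPs from the annotated pool (phenotype-associated SNPs
#' by default, as disease SNPs are by definition reported associations)
#' and assigns each 2-3 synthetic association studies. Per-study
#' likelihood ratios follow a multiplicative allelic odds ratio `psi`
#' drawn from `or_range`: with control genotypes at Hardy-Weinberg
#' frequencies of the SNP's risk allele, `LR(g) = psi^g / c` where `c`
#' normalises the case genotype distribution. `or_range = c(1, 1)` gives
#' a neutral panel with every likelihood ratio equal to 1.
#'
#' Only SNPs whose matched resampling pool (same MAF bin and functional
#' category) has at least `min_pool` members are eligible, so the null
#' is always estimable at simulation scale.
#'
#' @param annotations Pool annotations from [simulate_annotations()].
#' @param genotypes The simulated [genotype_matrix()].
#' @param n_snps Panel size.
#' @param or_range Range of per-SNP allelic odds ratios.
#' @param n_studies_range Studies per SNP (inclusive range).
#' @param sample_size_range Per-study sample sizes.
#' @param disease Disease label.
#' @param from_associated Restrict panel SNPs to phenotype-flagged SNPs.
#' @param min_pool Minimum matched-pool size for an eligible panel SNP.
#' @param maf_bin MAF bin width used for the eligibility check.
#' @param seed Optional integer seed.
#' @return List with `panel` (a `disease_panel`) and `associations`
#'   (the synthetic association records the panel was built from).
#' @export
make_panel <- function(annotations, genotypes, n_snps = 15,
                       or_range = c(1.1, 1.5), n_studies_range = c(2, 3),
                       sample_size_range = c(500, 5000),
                       disease = "synthetic_disease",
                       from_associated = TRUE, min_pool = 10,
                       maf_bin = 0.02, seed = NULL) {
  pool_sizes <- matched_pool_sizes(annotations, maf_bin)
  eligible <- annotations$snp_id[pool_sizes >= min_pool]
  if (from_associated) {
    eligible <- intersect(eligible,
                          annotations$snp_id[annotations$phenotype_associated])
  }
  if (length(eligible) < n_snps) {
    abort(sprintf(
      "panel of %d SNPs requested but only %d eligible pool SNPs (matched pool >= %d%s)",
      n_snps, length(eligible), min_pool,
      if (from_associated) ", phenotype-associated" else ""))
  }
  f_counted <- pooled_frequency(genotypes)
  study_pops <- c("European", "Asian", "African", "American")
  with_seed_or_not(seed, {
    snp_ids <- sample(eligible, n_snps)
    records <- purrr::map_dfr(snp_ids, function(s) {
      risk_allele <- sample(c("A", "B"), 1)
      q <- if (risk_allele == "A") f_counted[[s]] else 1 - f_counted[[s]]
      psi <- runif(1, or_range[1], or_range[2])
      lr <- allelic_lr(psi, q)
      k <- sample(seq(n_studies_range[1], n_studies_range[2]), 1)
      tibble::tibble(
        snp_id = s,
        disease = disease,
        study_population = sample(study_pops, k),
        sample_size = round(runif(k, sample_size_range[1], sample_size_range[2])),
        lr_hom_risk = lr[3], lr_het = lr[2], lr_hom_protective = lr[1],
        p_value = 10^-runif(k, 6.05, 12),
        risk_allele = risk_allele
      )
    })
    combined <- suppressMessages(combine_likelihood_ratios(records))
    panel <- build_panel(combined, annotations, genotypes, disease = disease)
    list(panel = panel, associations = records)
  })
}

# LR(g) for g = 0, 1, 2 risk alleles under a multiplicative allelic odds
# ratio psi and risk-allele frequency q in controls (Hardy-Weinberg).
allelic_lr <- function(psi, q) {
  if (psi == 1) return(rep(1, 3))     # neutral effect, exactly
  hwe <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  psi^(0:2) / sum(hwe * psi^(0:2))
}

# Size of each SNP's matched pool (same MAF bin + category, self excluded).
matched_pool_sizes <- function(annotations, maf_bin = 0.02) {
  bin <- maf_bin_index(annotations$global_maf, maf_bin)
  cell <- paste(bin, annotations$functional_category)
  as.integer(table(cell)[cell]) - 1L
}

#' Inject a risk-differentiation event on a tree branch
#'
#' Shifts the risk-allele frequency of every panel SNP by `delta` in all
#' populations descending from the chosen branch; non-panel pool SNPs
#' are untouched. Shifted frequencies are clamped to `[0.01, 0.99]`
#' (with a warning) and the clamped SNPs are recorded in the truth
#' table.
#'
#' @param freqs Frequency tibble from [simulate_frequencies()].
#' @param tree The population tree the frequencies were simulated on.
#' @param branch Branch id (see [population_branches()]).
#' @param delta Risk-allele frequency shift; positive increases risk in
#'   the descendants.
#' @param panel A `disease_panel` (provides risk-allele orientation).
#' @return List with `frequencies` (shifted tibble) and `truth` (a
#'   tibble: `event_branch`, `delta`, `direction`,
#'   `affected_populations`, `shifted_snps`, `clamped_snps` —
#'   the last three are list-columns).
#' @export
inject_event <- function(freqs, tree, branch, delta, panel) {
  branches <- population_branches(tree)
  if (!branch %in% branches$branch) {
    abort(paste0("branch not in tree: ", branch))
  }
  affected <- branches$descendants[[match(branch, branches$branch)]]
  # shift of the counted ("A") allele: +delta where the risk allele is A
  sign_a <- ifelse(panel$risk_allele == "A", 1, -1)
  shift <- setNames(sign_a * delta, panel$snp_id)
  idx <- freqs$population %in% affected & freqs$snp_id %in% panel$snp_id
  new_freq <- freqs$freq
  new_freq[idx] <- new_freq[idx] + shift[freqs$snp_id[idx]]
  clamped_rows <- idx & (new_freq < 0.01 | new_freq > 0.99)
  if (any(clamped_rows)) {
    warn(sprintf("inject_event: %d shifted frequencies clamped to [0.01, 0.99]",
                 sum(clamped_rows)))
    new_freq[clamped_rows] <- pmin(pmax(new_freq[clamped_rows], 0.01), 0.99)
  }
  out <- freqs
  out$freq <- new_freq
  attr(out, "ancestral") <- attr(freqs, "ancestral")
  truth <- tibble::tibble(
    event_branch = branch,
    delta = delta,
    direction = ifelse(delta >= 0, "increased", "decreased"),
    affected_populations = list(affected),
    shifted_snps = list(panel$snp_id),
    clamped_snps = list(unique(freqs$snp_id[clamped_rows]))
  )
  list(frequencies = out, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper tying the generator together: tree, drifted
#' frequencies, an optional injected event, Hardy-Weinberg genotypes,
#' pool annotations and a disease panel. All stages draw reproducible
#' sub-seeds from `seed`. The defaults are the package's reference
#' simulation conditions (8 populations of 30, a 2,000-SNP pool, a
#' 15-SNP panel, per-branch drift `F = 0.05`).
#'
#' @param n_populations,n_per_pop,n_pool_snps,drift_f,panel_snps,or_range
#'   Generator parameters.
#' @param missing_rate Genotype missingness rate.
#' @param event Optional list `list(branch =, delta =)` naming the event
#'   branch and the risk-allele frequency shift.
#' @param tree Optional tree to use instead of a simulated one.
#' @param phenotype_fraction Passed to [simulate_annotations()].
#' @param seed Integer master seed.
#' @return List with `tree`, `frequencies`, `genotypes`, `annotations`,
#'   `panel`, `associations`, and `truth` (`NULL` without an event).
#' @export
simulate_cohort <- function(n_populations = 8, n_per_pop = 30,
                            n_pool_snps = 2000, drift_f = 0.05,
                            panel_snps = 15, or_range = c(1.1, 1.5),
                            missing_rate = 0, event = NULL, tree = NULL,
                            phenotype_fraction = 0.07, seed = NULL) {
  tree <- tree %||% simulate_population_tree(n_populations, derive_seed(seed, 1))
  freqs <- simulate_frequencies(tree, n_pool_snps, drift_f,
                                seed = derive_seed(seed, 2))
  # annotations and the panel are derived from pre-event genotypes so the
  # injected shift changes frequencies, not the matching structure
  genotypes0 <- simulate_genotypes(freqs, n_per_pop, missing_rate,
                                   seed = derive_seed(seed, 3))
  annotations <- simulate_annotations(genotypes0,
                                      phenotype_fraction = phenotype_fraction,
                                      seed = derive_seed(seed, 4))
  made <- make_panel(annotations, genotypes0, n_snps = panel_snps,
                     or_range = or_range, seed = derive_seed(seed, 5))
  truth <- NULL
  genotypes <- genotypes0
  if (!is.null(event)) {
    inj <- inject_event(freqs, tree, event$branch, event$delta, made$panel)
    freqs <- inj$frequencies
    truth <- inj$truth
    genotypes <- simulate_genotypes(freqs, n_per_pop, missing_rate,
                                    seed = derive_seed(seed, 3))
  }
  list(tree = tree, frequencies = freqs, genotypes = genotypes,
       annotations = annotations, panel = made$panel,
       associations = made$associations, truth = truth)
}
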