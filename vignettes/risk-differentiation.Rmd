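---
title: "Testing polygenic risk differentiation against genetic drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing polygenic risk differentiation against genetic drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskdrift)
```

## The question and the model

Allele frequencies of the SNPs that tag a complex disease drift apart as
populations separate, so a polygenic risk score differs between
populations even when nothing disease-specific ever happened. The method
implemented here treats drift as the null hypothesis and asks, branch by
branch of a rooted population phylogeny, whether the observed risk-score
difference between the populations below a branch and those above it
exceeds what random panels of comparable SNPs produce.

### Risk scores

Effect sizes arrive as per-study, per-genotype likelihood ratios
`LR_i(g)` (or case/control genotype probabilities, whose ratio is
taken). They are merged per SNP as a weighted mean with weights equal to
the square root of each study's sample size:

$$L(g) \;=\; \frac{\sum_i \sqrt{A_i}\, LR_i(g)}{\sum_i \sqrt{A_i}}.$$

An individual's risk is $r = \sum_{\text{SNPs}} \ln L(g)$ over the
disease's panel, a population's risk is the mean over its members, and
the difference between two groups is a difference of such means. Three
conventions matter:

* **Natural logarithm.** The log base is a uniform rescaling of every
  score; natural log makes $r$ the log of a product of likelihood
  ratios.
* **Missing genotypes contribute nothing** (a factor of 1). Missingness
  is absent evidence, never evidence of the protective genotype, and is
  carried as a distinct sentinel end to end.
* **Genotypes count risk-allele copies**, so `L` lookup is unambiguous;
  pool SNPs count minor-allele copies.

SNP inclusion follows the standard evidence rules for curated GWAS
associations: an association p-value
below $10^{-6}$, detection in at least two distinct study populations,
computable genotype likelihood ratios, and greedy LD pruning at
$r^2 \ge 0.2$ (panel order, first kept wins; $r^2$ on genotype dosages
over the pooled cohort by default, overridable per population;
monomorphic SNPs, whose $r^2$ is undefined, are kept with a note).
Restricting the association records to one study-population group and
recombining (`restrict_to_study_populations()`) reproduces the
"population-specific effect size" sensitivity analysis; panel SNPs left
without records simply drop out.

### The matched resampling null

For a branch $i$, the observed statistic is
$O_i = \overline{r}_{\text{ancestral}} - \overline{r}_{\text{descendant}}$
(individual-weighted means). Under the null, every panel SNP is replaced
by a SNP drawn uniformly from its **matched pool**: all genotyped SNPs
in the same global minor-allele-frequency bin and the same functional
category (frameshift, nonsense, missense, untranslated, near-gene,
intron, coding-synonymous, unknown). The replacement inherits the
original SNP's combined likelihood ratios, oriented so that its risk
allele has the original's major/minor status — only the allele-frequency
structure is randomised, which is exactly the drift question. One
replacement panel is shared by **all** branches within a draw, so the
null matrix `r[i, k]` (branches × K draws) preserves the correlation of
risk between related populations; K defaults to 2,000 in the package;
at genome scale, with a 650,000-SNP pool, 100,000 draws are feasible
and set the attainable p floor at 1e-5.

Numerical choices, each of which a user can change:

* **MAF bins of width 0.02.** Narrow enough to control frequency, wide
  enough to keep pools populated; the matching requirement itself fixes
  no tolerance.
* **A panel SNP is excluded from its own pool**, so the observed
  statistic cannot contaminate its null.
* **Empirical p is the exceedance fraction in the observed direction,
  floored at 1/K** — 15 more-extreme draws out of 100,000 report
  p = 1.5e-4, zero report 1e-5, never 0. A two-sided option
  (`2 * min(tails)`, capped at 1) is exposed.
* **Sidedness and calibration.** Direction-specific p-values satisfy
  P(p ≤ a) = 2a under the null — each draw can be extreme in *its own*
  direction, so these p-values live on (0, ~0.5] at twice the uniform
  density and are *not* uniform. This direction-specific counting is
  the reporting convention the method uses, and it remains valid
  because the q-value applies the same convention to the null side. Calibration checks (uniformity of p on event-free cohorts)
  therefore use the two-sided option, which is exactly uniform; with the
  one-sided default the corresponding statement is that twice the
  fraction of branches below a/2 is a.
* **q-values.** For an observed branch p-value $\alpha$,
  $N(\alpha)$ counts observed branches at or below $\alpha$ and
  $E[N(\alpha)]$ is the mean number of branches per null draw reaching
  $\alpha$, each draw scored against its own branch's full null
  distribution (including itself — simple and exact under
  exchangeability). $q = \min(1, E[N(\alpha)]/N(\alpha))$ corrects
  across the correlated branches tested without assuming independence.
* **Root handling.** The two branches leaving the root induce the same
  population partition with the roles of the two sets swapped; the one
  with the larger descendant set is suppressed to avoid double counting.
  The root itself (empty ancestral set) is never a testable branch.

`population_vs_rest()` is the two-set special case — one population
against all others combined — using identical machinery, with q
correcting across the populations tested.

### Event inference

An ancestral differentiation event passes its shifted risk to every
branch below it, so an event on branch $z$ *explains* $z$ and its
subtree. With $P$ the vector of branch null probabilities, the model
log-likelihood of an event set is

$$\ell(z_1,\dots,z_y) \;=\; \sum_{\text{unexplained } k} \ln P(k),$$

the simplest form consistent with the method's constraints: explained
branches stop contributing surprise, unexplained branches should look
like drift. Admissible sets contain no event inside another event's
subtree (a nested event explains nothing new); the default search is
exhaustive over admissible y-subsets with ties broken toward the set
explaining fewer branches, then lexicographically. A greedy stepwise
search is provided for trees where $\binom{B}{y}$ is infeasible (at the
51-population scale with $y \ge 4$); on dominant-signal problems the two
agree, and the exhaustive route is pinned against an independently coded
recursive oracle in the test suite. The number of events is chosen by
nested likelihood-ratio tests, $2(\ell_n - \ell_{n-1}) \sim \chi^2_1$,
stepping up from $n = 2$ and stopping at the first non-significant
improvement (default threshold 0.05). The candidate sequence is
truncated once an event set explains every branch: beyond full coverage
admissibility can only force worse sets, and before it the best
log-likelihood is non-decreasing.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the statistical structure the null
assumes: populations related by a tree, allele frequencies drifted from
shared ancestral values, Hardy–Weinberg genotypes within populations, an
annotated genome-wide pool, and disease panels with study-level effect
sizes.

**Drift model.** Each edge applies a Balding–Nichols step: the child
frequency is Beta-distributed with mean equal to the parent frequency
$p$ and variance $f_e\,p(1-p)$. Because these variances compose
multiplicatively in $1-f$, the per-edge coefficients are set to
$f_e = 1-(1-F)^{t_e/T}$ (edge length $t_e$, tree depth $T$), so that on
an ultrametric tree **every population sits at total divergence exactly
$F$ from the ancestor** — `drift_f` is the leaf-level fixation index,
the quantity Weir–Cockerham Fst on the pool SNPs estimates, while the
tree shape controls the correlation structure. Simulated trees are
coalescent (`ape::rcoal`), hence ultrametric; trees without branch
lengths get unit lengths, so a star tree is one Balding–Nichols step of
size $F$ per population. Ancestral frequencies are uniform on
[0.05, 0.95] to avoid boundary fixation and keep MAF bins populated.
The estimator checks run on a star phylogeny, where all populations are
exchangeable at divergence $F$ — the configuration in which
"Fst ≈ drift_f" is exact rather than approximate.

**Panels.** Panel SNPs are drawn from the phenotype-associated pool
(disease SNPs are by construction reported associations) among SNPs
whose matched pool has at least `min_pool = 10` members — at genome
scale pools are always populated; at simulation scale rare functional
categories would otherwise make the null inestimable. Each SNP gets 2–3
synthetic studies (a single-study SNP could never pass the two-
population detection rule), sample sizes uniform on [500, 5000],
p-values below $10^{-6}$, and per-genotype likelihood ratios from a
multiplicative allelic odds ratio $\psi$ drawn uniformly from
[1.1, 1.5] — the typical effect-size range of common-variant GWAS hits,
and consistent with per-individual score ranges of a few log units over
10–30 SNPs. `or_range = c(1, 1)` produces an exactly neutral panel. The
phenotype-associated fraction defaults to 0.07, the genome-wide ratio of
reported-association SNPs to genotyped SNPs.

**Events.** `inject_event()` shifts the risk-allele frequency of every
panel SNP by $\delta$ in all populations below a chosen branch,
clamping to [0.01, 0.99] with a warning and recording clamped SNPs in
the truth table; configurations should choose $\delta$ so the shift
stays in bounds.

What the generator does **not** emulate, and what passing tests
therefore do not establish about real data: linkage disequilibrium
between pool SNPs (LD fixtures for the pruning test are explicit
duplicated or partially flipped columns, not genealogical), admixture
and migration after the split, ascertainment structure of genotyping
arrays, non-equilibrium demography (bottlenecks, expansions), and
heterogeneous true effect sizes across populations. Real-data inference
additionally inherits whatever biases the association database carries.

## Identifiability of event locations

A genuinely subtle limitation, visible in simulation: an event on a
mid-tree branch $T$ also shifts the contrast of *every other* branch,
because the shifted populations enter the ancestral-set means of
branches elsewhere in the tree, and in particular the parent of $T$
genuinely deviates (its descendant set contains the shifted
populations). With a strong event, the parent's p-value reaches the
floor alongside the target's, and the coverage likelihood — which
rewards explaining more floored branches — prefers the parent. Exact
single-branch attribution is therefore reliable only for branches
without a testable parent partition, i.e. the root clades (the only
branches that have a same-partition sibling); elsewhere the inferred
event should be read as "this clade or its immediate ancestry". For the
same reason the stepwise LRT often supports more than one event after a
single injected shift: the complementary side of the tree genuinely
deviates in the opposite direction, and the model correctly reports
that one event on the target branch does not explain it. The package's
recovery checks inject events on a balanced root clade accordingly.

## Robustness stages

* **Outliers** (`remove_outliers()`): per population, individuals whose
  risk deviates more than 1.5 interquartile ranges from the median are
  removed (quantile type 7; a zero-IQR population keeps only members at
  the median, with a warning) and the test is rerun on the remainder.
* **Ascertainment control** (`ascertainment_pool()`): the resampling
  pool is restricted to SNPs reported associated with *any* phenotype,
  countering the enrichment of disease SNPs in well-tagged regions;
  retained and discarded counts are reported, as every filter in the
  package reports counts in and out.
* **Fst comparison** (`global_fst()`, `fst_rank_p()`,
  `combine_rank_p()`): the Weir–Cockerham (1984) multi-population
  $\theta$ — the standard sample-size-corrected estimator, with
  negative estimates kept and monomorphic SNPs excluded — is
  rank-normalised within MAF bins (fraction of same-bin SNPs with
  strictly lower $\theta$) and combined across panel SNPs by Fisher's
  method on upper-tail p-values, floored at one over the bin size
  (Stouffer's Z behind a flag). Per-SNP ranking dilutes a correlated
  shift confined to one clade across the genome-wide Fst distribution,
  which is precisely the contrast with the set-level branch test.

## Problem sizes and tolerances used in the checks

The test suite and `scripts/acceptance.R` use, as the package's
reference simulation conditions: 8 populations × 30 individuals, a
2,000-SNP pool, 15-SNP panels, `drift_f = 0.05`, and `K = 2000` draws;
calibration runs 50 event-free replicates (two-sided p, KS uniformity
at the 1% level, fraction below 0.05), recovery runs 20 replicates with
$\delta = 0.15$ on a balanced-tree root clade, moment checks use 10,000
Balding–Nichols draws at $p = 0.3$, and the Weir–Cockerham pool check
uses 2,000 star-tree SNPs against a 10% relative error. Hand-verified
constants pin the arithmetic: the $\sqrt{A}$-weighted likelihood-ratio
mean, the two-population $\theta = 0.2888889$ toy, the $\chi^2_1$
p-values of the worked event-count examples, and Fisher's combination
of two p = 0.5 values (0.5966). Results files round-trip bit-exactly:
doubles are written with 17 significant digits and re-parsed with base
R's correctly-rounded reader, and identical seeds reproduce
byte-identical output files.
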