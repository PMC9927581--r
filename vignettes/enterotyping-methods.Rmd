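---
title: "Enterotype discovery and downstream statistics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enterotype discovery and downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enterotyper)
```

## The problem

Gut microbial communities vary so much between individual animals that
per-taxon comparisons against a single covariate are often uninterpretable.
Enterotyping addresses this by first stratifying the cohort into a small
number of community types — clusters of samples occupying "highly populated"
regions of composition space — and then asking how host phenotypes, taxa,
and microbial interaction structure differ *between* those types.
`enterotyper` implements that full chain for amplicon-style abundance
tables: enterotype discovery, diversity statistics, two-group differential
abundance, microbe–trait association, and per-enterotype co-occurrence
networks, with a synthetic-cohort generator so that every stage can be
validated against known ground truth.

## Enterotype discovery

**Distance.** Samples are compared with the square root of the
Jensen–Shannon divergence between their relative-abundance profiles,

$$d(P, Q) = \sqrt{\tfrac12 KL(P \,\|\, M) + \tfrac12 KL(Q \,\|\, M)},
\qquad M = (P + Q)/2,$$

with natural logarithms, so $d$ is a metric bounded by $\sqrt{\ln 2}$.
Zero abundances would make a Kullback–Leibler term infinite, so zeros are
replaced by a pseudocount (default `1e-6`, small relative to any observable
abundance at realistic sequencing depth) and each profile renormalized. The
choice of zero-handling is ours; results are insensitive to the pseudocount
over several orders of magnitude because it only affects taxa absent from
one of the two samples.

**Clustering.** `pam_cluster()` is k-medoids on the precomputed distance
matrix. Two regimes, both fully deterministic:

* when the number of candidate medoid sets $\binom{n}{k}$ is at most
  `exact_limit` (default 20 000, which covers $k = 2$ up to $n = 200$ and
  everything with $n \le 10$), the globally optimal medoid set is found by
  exhaustive enumeration. We adopted this after measuring that single-swap
  local search stops at a non-global local optimum on roughly 6–12% of
  small random instances — an avoidable failure mode when enumeration is
  this cheap;
* otherwise, greedy BUILD (each new medoid minimizes the total
  nearest-medoid distance) followed by steepest-descent SWAP (repeatedly
  apply the single (medoid, non-medoid) exchange with the largest strict
  objective decrease). Ties always break toward the lowest sample index, so
  there is no dependence on a random number generator anywhere in the
  clustering.

**Model selection.** `enterotype()` scans `k_range` (default 2–10, a range
wide enough that the CH curve's decay is visible) and keeps the $k$
maximizing the Calinski–Harabasz index

$$CH = \frac{B/(k-1)}{W/(n-k)},$$

with $B$ and $W$ the between/within sums of squared deviations from
centroids. CH is defined for Euclidean geometry, so samples are embedded by
principal-coordinate analysis and sums of squares taken over all
positive-eigenvalue axes; this keeps the index well-posed for any input
dissimilarity and makes it checkable against a from-scratch evaluation on
fixed coordinates. Whether one computes CH on the raw dissimilarities or an
embedding is a genuinely open choice; we prefer the embedding because the
index's variance decomposition is only meaningful there. Ties across $k$ go
to the smallest $k$.

**Drivers.** The "driver" of an enterotype is operationalized as the
feature with the highest mean relative abundance among that cluster's
samples (ties: lexicographically smallest ID). Both clusters may share a
driver. `identify_drivers()` returns the full ranked contribution list, not
just the winner.

## Diversity

`alpha_diversity()` works on integer counts only — richness estimators are
undefined on relative data. Per sample it reports observed richness (Sobs),
Shannon entropy in nats, both Simpson conventions (dominance $\sum p_i^2$
and diversity $1 - \sum p_i^2$; toolchains disagree about which one is
"the" Simpson index, so neither is silently chosen), the classic Chao1

$$\hat S = S + F_1^2 / (2 F_2),$$

with the fallback $S + F_1(F_1-1)/2$ when there are no doubletons, and ACE
with the standard rare-taxon cutoff of 10 (falling back to Chao1 when the
rare-group coverage estimate is zero). We use the classic Chao1 form rather
than a bias-corrected variant so that the estimator has the familiar closed
form; on the worked example $S=10$, $F_1=4$, $F_2=2$ it returns exactly 14.

Beta diversity uses Bray–Curtis (`vegan::vegdist`) with classical-scaling
PCoA; negative eigenvalues (possible for non-Euclidean dissimilarities) are
reported but excluded from coordinates and explained-variation shares.
`anosim_test()` is the rank permutation test
$R = (\bar r_B - \bar r_W)/(n(n-1)/4)$ with $p = (1 + \#\{R^* \ge R\})/(1 +
n_{perm})$; the permutation count (default 999) bounds the smallest
attainable p at $1/(n_{perm}+1)$ and the seed is part of the interface, so
a run is exactly reproducible.

## Two-group statistics

Phenotypes are compared with the two-sample t-test (Welch by default — we
see no reason to assume equal variances; the pooled form is available by
flag). Taxa and pathway tables use the Wilcoxon rank-sum test: exact
enumeration when $n_x + n_y \le 20$ without ties, otherwise the normal
approximation with tie-corrected variance and continuity correction.
Per-table p-values are adjusted with Benjamini–Hochberg, and the
`enriched_in` call is made on the adjusted q at level `alpha` (default
0.05). Feature selection before testing — "top N by mean abundance" or
"mean abundance above a percentage" — is applied to the overall mean across
all samples by default; a per-cluster variant is available because the
threshold's reference population is a genuine ambiguity in common practice.
Both raw p and q are always reported.

## Association and networks

`spearman_cor()` is mid-rank Pearson with the two-sided t approximation on
$n-2$ degrees of freedom; pairs with zero rank variance are an error (or
`NA` inside matrix-level wrappers, with a warning for constant traits).
`build_network()` applies, within the subgroup whose network is being
built: a node filter (mean relative abundance > 0.1% AND nonzero in more
than half of the subgroup samples) and an edge criterion
($|\rho| > 0.2$ and unadjusted $p < 0.05$, all inequalities strict). The
prevalence reference population is the subgroup, not the whole cohort,
because networks are constructed per enterotype; a whitelist argument
allows restricting nodes to, e.g., previously identified differential
genera. Because the statistic is rank-based, the edge set is invariant to
any strictly monotone transformation of a genus' abundances — a property
the test suite checks explicitly. Exports are SIF, GraphML (with rho/p edge
attributes), and a plain edge TSV, all in deterministic lexicographic
order.

## The synthetic cohort generator

`simulate_cohort()` draws, for each sample of component $c$,

$$p \sim \mathrm{Dirichlet}(\theta \cdot \mu_c), \qquad
  y \sim \mathrm{Multinomial}(D, p),$$

a standard overdispersed generative family for amplicon compositions. The
defaults define the study conditions the package is validated under:

* two components of 39 and 37 samples;
* a 27-genus panel (`goat_genus_panel()`) whose per-component means mirror
  the differential genus profile of a two-enterotype young-goat cohort —
  e.g. *Christensenellaceae R-7 group* at 3.17% vs 8.23% and *Prevotella*
  at 3.32% vs 0.93% — with the remaining mass pooled into an `"other"`
  feature so each mean vector is a proper composition;
* concentration $\theta = 200$, chosen once as moderate genus-level
  overdispersion: the within-component standard deviation of a genus at
  proportion $p$ is $\approx \sqrt{p(1-p)/(\theta+1)}$, which puts the
  large planted shifts at roughly 2–3 within-component standard deviations
  — clearly separated but far from noise-free;
* sequencing depth $D = 20\,000$ counts per sample, a typical amplicon
  library size at which multinomial noise is minor relative to the
  Dirichlet component;
* phenotypes drawn as $\mathcal N(\mu_{c}, \sigma)$ from
  `goat_phenotype_panel()`, with physiologically plausible goat-kid values,
  effect sizes of ~0.6–0.8 SD for the traits that differ between
  communities (growth rate, most fecal VFA, serum glucose and cholesterol
  fractions higher in community 1; IgG and urea nitrogen higher in
  community 2) and no shift for the null traits (intake, butyrate, fecal
  ammonia, globulin, total protein, triglycerides);
* optional rank coupling: a trait listed in the coupling map is generated
  through a Gaussian copula on one genus' realized abundance
  ($\epsilon = \rho\, z_{genus} + \sqrt{1-\rho^2}\,\epsilon'$), so Spearman
  recovery of microbe–trait association is well-posed by construction.

What the generator does **not** emulate: ASV-level sparsity (it works at
genus resolution), spatial/temporal autocorrelation, compositional
zero-inflation beyond what the Dirichlet-multinomial produces, sequencing
batch effects, and any read-level process. Passing tests therefore
demonstrate the statistical machinery is correct under a realistic
overdispersed compositional model — not that any particular real cohort
will cluster cleanly.

## Numerical choices and degenerate inputs

* All tie-breaks (PAM medoids, driver ranking, CH across $k$) are
  deterministic and documented above.
* $W = 0$ in the CH index (all points identical within clusters) returns an
  `Inf` sentinel with a warning rather than an error.
* Zero-variance groups in the t-test use the convention $p = 1$ for equal
  means, $p = 0$ otherwise; all-tied Wilcoxon inputs return $p = 1$.
* An all-zero sample is an error in `to_relative()` (no composition to
  speak of) and a pair of all-zero samples is an error in `bray_curtis()`
  (the denominator vanishes).
* Distance matrices are validated to be symmetric within 1e-12 with zero
  diagonal; small negative rounding artifacts are clipped.
* Relative tables must have columns summing to 1 within 1e-6 at the
  constructor boundary; `to_relative()` produces exact unit sums.

## Problem sizes used in validation

The test-suite simulations run at the default cohort geometry (76 samples,
28 features): 100 replicates for enterotype-recovery and planted-effect
checks, 1 000 replicates for the type-I-error calibration of the Wilcoxon
and ANOSIM tests (the latter at 99 permutations and $n = 16$, where the
permutation p-value's resolution matches the nominal level), 200 random
instances for the k-medoids optimality oracle, and 1 000 random triples for
the metric property of the Jensen–Shannon distance. These sizes give
binomial standard errors comfortably inside the asserted bands while
keeping the full suite around two minutes.

## Known limitations

* The heuristic PAM path is a local search; its optimality guarantee
  applies only below `exact_limit`.
* The exact Wilcoxon route refuses ties rather than enumerating the
  tie-adjusted permutation distribution.
* CH on severely non-Euclidean dissimilarities discards
  negative-eigenvalue geometry.
* Network inference is marginal Spearman thresholding, deliberately: it
  mirrors the common practice it models, and makes no claim of recovering
  direct (conditional) interactions.
* No rarefaction or depth normalization is provided; counts go in as-is,
  and relative abundances are simple proportions.

## A worked run

```{r, eval = FALSE}
library(enterotyper)

cohort <- simulate_cohort(simulation_config(), seed = 1)
rel    <- to_relative(cohort$counts)
genus  <- aggregate_by_rank(rel, cohort$taxonomy, "genus")

fit <- enterotype(jsd_distance(rel))
glance(fit)                      # optimal_k, CH maximum, objective
autoplot(fit)                    # CH trace
autoplot(pcoa(bray_curtis(rel)), clusters = fit)

differential_table(genus, fit, selector = list(min_mean_pct = 1))
net1 <- build_network(genus,
  samples = tidy(fit)$sample_id[tidy(fit)$cluster == 1])
glance(net1)
```

Or in one call, writing every artifact plus a plain-text report:

```{r, eval = FALSE}
run_pipeline(list(n_perm = 999), out_dir = "cohort_run", seed = 1)
```
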