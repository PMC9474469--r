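---
title: "Local similarity networks from replicated microbiome time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local similarity networks from replicated microbiome time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elsanet)
```

`elsanet` infers time-delayed co-occurrence networks from replicated OTU
time series and compares those networks across experimental treatments.
This vignette is the package's account of the underlying methods: the
statistics it computes, the synthetic data it tests itself on, the
defaults it ships with and why, and what its guarantees do and do not
cover.

## The local similarity statistic

Two OTU trajectories are compared after replicate averaging: within one
treatment, the replicates at each generation are collapsed to their
mean (`build_series()`), which is what extends plain local similarity
analysis to replicated designs. Each trajectory is then normalized —
by default through rank-based normal scores, where the value at rank
$r$ of $n$ maps to $\Phi^{-1}(r/(n+1))$ with averaged ranks for ties.
Normal scores make the statistic invariant to monotone distortions of
abundance (compositional scaling, sequencing-depth effects) and give
every OTU the same marginal, so the permutation null is exchangeable.
Ordinary z-scoring and no transform are available.

For normalized series $x, y$ of length $n$ and a delay bound $D$, the
score is computed by a dynamic program over aligned index pairs
$(i, j)$ with $|i - j| \le D$:

$$P^{+}_{i,j} = \max(0,\; P^{+}_{i-1,j-1} + x_i y_j), \qquad
  P^{-}_{i,j} = \max(0,\; P^{-}_{i-1,j-1} - x_i y_j),$$

local alignment in the signal-processing sense: a run of consistently
same-signed (or consistently opposite-signed) co-variation accumulates,
and resets when it turns against itself. The local similarity score is
the maximum cell of either table divided by $n$; the sign records which
table attained it, and the delay is $j - i$ along the maximizing run
(constant within a run, since runs move diagonally). Both tables are
scanned so positive and negative associations are found symmetrically.

Tie-breaking is deterministic and documented: a tie between the
positive and negative table goes to the positive sign; ties among
equally scoring runs go to the smallest $|{\rm delay}|$, then to the
positive delay. The DP is exact — the test suite checks it against an
oracle that enumerates every pair of aligned contiguous runs.

### Significance

The p-value of a pair is the probability that a random permutation of
one series attains at least the observed score. For series of length
$\le$ `exact_below` (default 6) all $n!$ orderings are enumerated
(identity included, $p = \#\{LS_{\rm perm} \ge LS_{\rm obs}\}/n!$);
otherwise `n_perm` Monte-Carlo permutations are drawn and
$p = (\#\{\ge\} + 1)/(n_{\rm perm} + 1)$. Permuting one series is
distributionally equivalent to permuting both. Each OTU pair draws its
permutations from a stream seeded by (run seed, otu_a, otu_b), so
results are independent of evaluation order and of which other OTUs
are present.

An optional conservative upper bound on the p-value is reported as
$\min(1, p \cdot (2D + 1))$ — a Bonferroni-style correction across the
delay offsets. It is a deliberately simple stand-in, not the asymptotic
tail approximation some LSA implementations use; the permutation
p-value is the primary quantity everywhere in this package.

### Edge calls

A treatment's network has as nodes the *shared* filtered OTU set — OTUs
reaching at least 1% relative abundance in any sample of any treatment
— so all treatment networks are directly comparable, isolated nodes
included in every density denominator. The default rule draws an edge
when $p \le \alpha$. The protocol this package models can also be read
literally as drawing an edge when the p-value upper bound *exceeds* the
threshold; that inverted rule is available (`build_network(rule =
"inverted")`) but is never the default, because with the standard rule
the reported network contrasts are monotone in $\alpha$ and the
$\alpha$-robustness scan (`alpha_scan()`) has its usual meaning.

## Network summaries

Modularity uses the Newman–Girvan quantity
$Q = \sum_c (e_c/m - (d_c/2m)^2)$; the default optimizer is fast-greedy
agglomeration (deterministic), with Louvain available behind a seed.
Density is $2|E| / (|V|(|V|-1))$ over the full node set. Average path
length is averaged over connected, distinct node pairs only — these
networks are routinely disconnected — and the count of excluded
(unreachable) pairs is always reported next to it. Exclusive edges
between two networks on the same node set are counted by endpoint pair
only, ignoring sign and score. Graph bookkeeping is delegated to
igraph; the test suite cross-checks density, path lengths and component
structure against an independent breadth-first-search implementation.

## Community statistics

The composition-level statistics around the network pipeline are the
field's standard ones, computed through vegan and base R: rarefaction
to a common depth (single draw per sample, without replacement),
Shannon diversity with the natural log, Bray–Curtis distances, classical
PCoA (negative eigenvalues dropped; percent variance over positive
eigenvalues only), and PERMANOVA with sequential sums of squares for
the crossed generation × treatment model with free permutation of
sample labels (999 by default). Pairwise treatment contrasts of Shannon
diversity are plain Welch t tests on per-sample indices. Family-level
aggregation ranks families by grand-mean relative abundance, keeps the
top k (default 7) and pools the remainder as "Other"; the heatmap
prefilter keeps OTUs whose maximum abundance reaches 7.5%.

## The synthetic-data generator

There is no public ground truth for microbial interaction networks, so
the package tests itself on data it generates with known structure.
`sim_config()` emulates a host-mediated selection study: 3 treatments ×
8 generations × 8 replicates (192 samples), 120 OTUs, 3000 reads per
sample, of which roughly 80–90 OTUs pass the 1% node filter — the scale
of the study design it mirrors (186 samples, ~90 network nodes,
rarefaction minimum 2988).

The latent model, per treatment:

* **Baseline composition.** A sorted symmetric Dirichlet draw gives the
  rank-abundance curve; the `evenness` parameter is the total Dirichlet
  concentration. One shared set of uniforms is pushed through each
  treatment's Dirichlet quantile function, so treatments reshape a
  *common* source community rather than drawing unrelated ones — the
  experimental design the generator mimics starts all treatments from
  one soil inoculant. This also makes the realized diversity ordering
  follow the evenness ordering rather than baseline-draw luck.
* **Shared environmental forcing.** The community-wide factor, one
  factor per planted module, and one factor per planted pair are
  stationary AR(1) trajectories (smoothing `ar_smoothing`, default 0.1)
  drawn *once* and reused by every treatment: all treatments sit in the
  same growth chamber on the same schedule. Treatments differ in how
  strongly their taxa couple to these shared trajectories
  (`connectivity_scale`), and in their own idiosyncratic and
  observation noise. Between-treatment network contrasts therefore
  reflect the coupling parameters, not independent factor-realization
  luck — the common-random-numbers design that any simulation-based
  comparison of configurations would use.
* **Planted modules.** Members load on their module factor with
  loading $\sqrt{r}$ (within-module correlation $r$, default 0.95
  before scaling) and *alternating signs*. Sign-mixing keeps a module
  mass-balanced: a block of taxa all rising together would swing the
  compositional denominator and induce spurious associations among all
  unrelated OTUs (a closure artifact, not an interaction), which the
  alternating design avoids while leaving $|{\rm corr}|$ between
  members unchanged — association networks treat positive and negative
  edges symmetrically. The default is eight modules of eight members:
  many small blocks give many independent factor draws, so no single
  unlucky trajectory erases a treatment's planted signal.
* **Module linking.** Each module factor blends in the community-wide
  factor with weight `module_link` (default 0.65, scaled by
  connectivity), interlinking the modules into one densely connected
  cluster at high connectivity — the feature that drives modularity
  *down* and path length *down* in the strongly coupled treatment, as
  observed in selection experiments.
* **Planted pairs.** Ten pairs at $\rho = 0.95$ (seven synchronous,
  three lag-1; a lag shifts one member's factor by one generation).
  Pairs occupy the most abundant ranks so pairwise recovery measures
  the statistic's power, not counting noise. Negative $\rho$ negates
  one member's deviations.
* **Observation model.** Latent log-abundance = baseline + latent
  deviation (SD `sigma_latent` = 1) + lognormal replicate noise (SD
  `sigma_replicate` = 0.4); softmax to a composition; multinomial
  counts at the configured depth. All randomness flows from one seeded
  stream in a documented draw order.

`treatment_gradient_preset()` grades `connectivity_scale` from 1 down
to 0.3 with convex spacing (detection power is convex in the latent
correlation, so linear spacing would bunch the weak levels) and
`evenness` from 45 up to 75, producing the qualitative signature the
pipeline should recover: density(high) > density(random) >
density(control) across the α scan, lower modularity and shorter paths
for the high-connectivity treatment, and a Shannon-diversity ordering
with contrasts of a few percent.

### What the generator does not emulate

Real amplicon data have features the generator omits deliberately:
taxon-specific PCR/primer bias, overdispersion beyond lognormal ×
multinomial, zero inflation from detection limits, phylogenetic
correlation among taxa, and the actual inoculant-passaging feedback
loop between generations (host selection acting on community
composition). Passing tests therefore demonstrate that the pipeline
recovers the structure this model plants at realistic scale and noise —
not that any particular real community has that structure.

## Numerical and design choices

* Exact-enumeration cutoff at $n \le 6$ (720 permutations) balances
  exactness against cost; at the study scale ($n = 8$ generations)
  Monte-Carlo with 1000 permutations is used, so the smallest
  attainable p is ~0.001.
* Score comparisons in the permutation loop use a $10^{-9}$ slack so
  that permutations reproducing the observed score by a different
  floating-point summation order still count as ties (conservative).
* With eight time points the permutation test's power is intrinsically
  modest: a perfectly correlated pair typically lands at $p \approx$
  0.002–0.01, so recall of planted $\rho = 0.95$ pairs at
  $\alpha = 0.01$ averages ~0.44 (calibrated over ten seeds). That is
  a property of short replicated series, not an implementation defect,
  and it is why the acceptance checks score recall against a
  pre-recorded calibration threshold rather than a round number.
* The constant-series z-score is refused with a pointer to normal
  scores (where an all-tied series maps to all zeros).
* PERMANOVA permutations, rarefaction draws, module detection and
  layout all take explicit seeds; `run_pipeline()` checksums every
  output so end-to-end determinism is testable.
* Problem sizes used by the test suite: the DP/permutation oracles run
  at $n \le 8$; null calibration uses 2000 independent pairs; the
  gradient signature check runs the full pipeline on 20 seeds at the
  default 192-sample, 120-OTU scale; pipeline determinism is checked on
  the same scale.

## Limitations

* The delay bound is small and integer (default 1 generation); series
  on irregular time grids are out of scope.
* The p-value upper bound is a labelled stand-in (delay-window
  Bonferroni), not the published asymptotic approximation.
* Modularity values from unweighted greedy optimization depend on the
  algorithm; cross-study comparisons of absolute Q are not meaningful,
  only within-study contrasts under a fixed method.
* The multiple-testing stance mirrors common practice for these
  networks: raw α thresholds with an α-robustness scan. A
  Benjamini–Hochberg adjusted column is trivial to add from the result
  tibbles (`p.adjust(res$p_value, "BH")`) but is not applied by
  default.
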