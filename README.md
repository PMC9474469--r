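# elsanet

Time-delayed co-occurrence networks from replicated microbiome time
series, built around extended Local Similarity Analysis (eLSA).

## The problem

Host-mediated microbiome selection experiments follow microbial
communities across generations of a host plant: several treatments
(e.g. selection for high host biomass, random selection, an unselected
control), each resampled at every generation with replicated pots, each
sample a 16S amplicon OTU count vector. The scientific questions are
about *interactions*: do taxa co-vary — possibly with a one-generation
lag — and does selection rewire the co-occurrence network (more edges,
denser, shorter paths, less modular)?

Plain correlation misses associations that hold only over part of the
time course or at a lag. Local similarity analysis scores the best
locally aligned run of two series; its extended form (eLSA) first
collapses replicates at each time point to their mean so replicated
designs can be used. `elsanet` implements that pipeline end to end:

* **LSA core** — for normalized series *x*, *y* and a delay bound *D*,
  a dynamic program over aligned index pairs (i, j), |i − j| ≤ D:

  P⁺[i,j] = max(0, P⁺[i−1,j−1] + xᵢyⱼ),  P⁻[i,j] = max(0, P⁻[i−1,j−1] − xᵢyⱼ)

  LS = (max over both tables)/n, with a sign and the delay j − i of the
  maximizing run. Significance comes from permutation: exact n!
  enumeration for short series, Monte-Carlo with the add-one correction
  otherwise (compiled in C++).
* **Networks** — per treatment, a graph on the shared node set (OTUs
  reaching ≥ 1% relative abundance in any sample), edge iff p ≤ α;
  degree distributions, greedy/Louvain modularity Q, density, average
  path length, exclusive-edge counts, and an α-robustness scan.
* **Community statistics** — rarefaction, Shannon diversity,
  Bray–Curtis distances, PCoA, PERMANOVA (via vegan), family-level
  aggregation and abundance filters.
* **Synthetic data** — a generator emulating the 3-treatment ×
  8-generation × 8-replicate design with planted pairwise associations
  (optionally lag-1), planted modules, a treatment-graded connectivity
  scale and a treatment-graded evenness, returning the ground truth for
  recovery scoring.

Everything is tidyverse-shaped: tables in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for figures.

## Worked example

```r
library(elsanet)

cfg <- treatment_gradient_preset(seed = 1)   # high > random > control signal
sim <- simulate_dataset(cfg)

rel   <- to_relative(sim$table)
nodes <- filter_prevalent_otus(rel, threshold = 0.01)

results <- lapply(
  stats::setNames(cfg$treatments, cfg$treatments),
  function(trt) all_pairs_lsa(build_series(nodes, trt), lsa_config(seed = 1))
)
networks <- lapply(
  stats::setNames(names(results), names(results)),
  function(trt) build_network(results[[trt]], otu_names(nodes),
                              alpha = 0.05, treatment = trt)
)

compare_networks(networks)$properties
#> # A tibble: 3 × 6
#>   treatment n_nodes n_edges density avg_path_length n_excluded_pairs
#>   <chr>       <dbl>   <dbl>   <dbl>           <dbl>            <int>
#> 1 high           78     302  0.101             3.03               77
#> 2 random         78     198  0.0659            3.35              372
#> 3 control        78     142  0.0473            3.98              153

detect_modules(networks$high)
#> greedy modularity partition: Q = 0.418, 6 modules (largest 22)

recovery_report(results, sim$truth, alpha = 0.01)
#> # A tibble: 3 × 7
#>   treatment n_planted n_called n_recovered recall precision sign_accuracy
#> 1 high             10       83           3    0.3    0.0361             1
#> 2 random           10       38           0    0      0                 NA
#> 3 control          10       30           0    0      0                 NA
```

Reading the output: of the 120 simulated OTUs, 78 reach the 1%
prevalence filter and form the shared node set. The high-connectivity
treatment's network is denser (0.101 vs 0.047), has shorter average
paths (3.0 vs 4.0 steps) and lower modularity than the control — the
qualitative signature of a community whose interactions intensified
under selection. Recovery is scored against the generator's planted
pairs; at a strict α = 0.01 with only eight time points, power per pair
is modest by design, and it degrades down the connectivity gradient
(the preset scales the planted correlation strength, so the weaker
treatments genuinely carry less signal).

A full run — simulate (or read a table), rarefy, filter, LSA per
treatment, networks, module detection, comparison table, α scan,
diversity/ordination/PERMANOVA, recovery — is one call:

```r
out <- run_pipeline(run_config(sim = cfg, seed = 1), "results/run1")
```

which writes every intermediate TSV/GraphML plus a checksum manifest
(identical config + seed ⇒ identical checksums). A thin shell wrapper
lives at `inst/scripts/elsanet-pipeline.R`.

## Vignette

`vignettes/elsa-networks.Rmd` documents the model, the generator's
latent design, parameter defaults and their rationale, numerical
choices, and known limitations.
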