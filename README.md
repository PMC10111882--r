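# nutrinet

Soil fungi and bacteria organise into **subcommunities** — modules of an
interkingdom co-occurrence network — and those subcommunities differ in
their genomic potential for carbon (C), nitrogen (N) and phosphorus (P)
cycling. `nutrinet` is an R package for deriving such subcommunities from
amplicon count tables and quantifying their predicted nutrient-cycling
potential, for microbial ecologists working with paired 16S/ITS surveys and
PICRUSt2-style predicted gene-family (EC) content.

The core quantity is the **functional abundance** of a unit *u* (a sample
or a network module) for enzyme *e*:

```
F[u, e] = Σ_t  a[u, t] · c[t, e]
```

where `a[u, t]` is the (mean) relative abundance of taxon *t* in *u* and
`c[t, e]` its predicted EC copy number — a matrix product linking community
structure to predicted function. Around this sit:

* **Network inference** — Meinshausen–Bühlmann neighborhood selection on
  CLR-transformed counts (coordinate-descent lasso in C++, 100-value λ
  path, minimum λ ratio 10⁻³) with StARS stability selection (50
  subsamples, instability threshold 0.05), one network per design cell
  (mycorrhizal type × tree-diversity level);
* **Subcommunity detection** — Clauset–Newman–Moore greedy modularity
  (igraph), centralities, bootstrap + Kolmogorov–Smirnov comparison of
  centrality distributions between networks;
* **Soil screen** — distance-based redundancy analysis (vegan `capscale`)
  of each module against standardised soil chemistry, with VIF filtering,
  a global-model gate and `ordistep` selection; modules with a significant
  final-model variable are "soil-responsive";
* **Statistics** — Shannon functional diversity with two-way ANOVA and BH
  post hoc tests, Bray–Curtis PERMANOVA across the seven nutrient
  combinations (C, N, P, CN, CP, NP, CNP), PCoA + envfit of enzymes onto
  module ordinations, paired Wilcoxon module comparisons, per-ASV
  differential functional abundance with class-level aggregation and
  Sankey export;
* **Synthetic data** — a generator with planted modules, planted
  soil–module associations and planted enzyme enrichments, plus ground
  truth, so the whole chain is testable without any sequencing data.

## Worked example

```r
library(nutrinet)

# simulate a small community: 6 design cells x 10 samples, 3 planted modules
b <- simulate_dataset(simulation_config(
  n_samples_per_cell = 10, n_bacteria = 60, n_fungi = 40,
  n_modules = 3, module_cohesion = 2.0,
  soil_effect_sizes = c(pH = 1.0),
  depth_bacteria = 3000, depth_fungi = 2000, seed = 5))

prep <- preprocess_bundle(b, depth_bacteria = 2500, depth_fungi = 1600,
                          abund_threshold = 0, seed = 1)
net <- stability_select(prep$merged, kingdom = prep$kingdom,
                        n_subsamples = 20, seed = 2)
net
#> mb_network : 100 nodes, 319 edges; lambda = 0.3064 (index 15 of 100 )

part <- detect_modules(net)
part
#> module_partition: 4 modules over 100 nodes; Q = 0.5896

score_partition_recovery(part$membership,
                         b$truth$modules[!is.na(b$truth$modules)])$ari
#> [1] 0.9146209
```

The network recovers the three planted modules (plus a residual group of
background taxa) with an adjusted Rand index of 0.91 against the planted
membership. Downstream, `module_soil_screen()` flags which modules track
soil chemistry, `module_functional_abundance()` gives each module's enzyme
profile, and `pairwise_module_tests()` / `differential_asvs()` /
`aggregate_to_class()` locate the taxa behind functional differences.
`run_pipeline(pipeline_config(...), out_dir)` chains all stages and writes
TSV/JSON reports plus a structured log.

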