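# coabnet

Co-abundance network analysis and taxonomic imbalance for multi-study gut
microbiome abundance tables.

## The problem

Gut microbiome surveys in inflammatory bowel disease (IBD: Crohn's disease,
CD, and ulcerative colitis, UC) show reduced diversity and abundance shifts
relative to healthy controls at several taxonomic ranks. A complementary,
relational question is which bacterial **families** rise and fall together
across thousands of samples, and where the IBD-altered families sit inside
that co-abundance structure. `coabnet` is for microbiome analysts who have
lineage-annotated count tables (OTU/ASV × sample, from one or many studies)
and want a reproducible, tested pipeline from those tables to:

* rank-level aggregation (phylum / class / family) and relative abundance;
* per-sample richness, Shannon diversity `H = -Σ p_i ln p_i` (nats), and
  analytic rarefaction curves
  `E[S_d] = S − Σ_i C(N−N_i, d) / C(N, d)`;
* fold-change classification of taxa between conditions:
  `fold = max(f, 1/f)` with `f = (mean_a + ε)/(mean_b + ε)`, called
  *changed* only when fold strictly exceeds a threshold (default 1.5);
* the core object: a **family–family co-abundance network**, connecting
  families whose relative abundances have Pearson `r > 0.3` and two-sided
  `p < 1e-10` (t transform, `n − 2` df), with
  * the **intra-phylum edge fraction** (share of edges joining families of
    the same phylum),
  * a random-graph null for it — analytic
    `E = Σ_p C(n_p, 2) / C(N, 2)` plus seeded Monte-Carlo draws — and
  * condition-specific subnetworks keeping edges with at least one
    most-abundant endpoint and at least one >1.5-fold-changed endpoint;
* a seeded synthetic multi-study generator with a phylum-block latent-factor
  model and planted condition folds, so every stage is testable against
  known ground truth.

Everything is tidyverse-shaped: one long tibble (taxon × sample rows) flows
through all stages; results come back as tibbles, `tidy()`/`glance()`
methods cover the network and null objects, and `autoplot()`/`plot_*()`
give quick ggplot2 graphics.

## Worked example

```r
library(coabnet)

ds  <- generate_ibd_cohort(seed = 1, n_per_condition = 200)
rel <- to_relative(ds$table)

head(diversity_summary(ds$table), 3)
#> # A tibble: 3 × 5
#>   sample_id study_id condition richness shannon
#>   <chr>     <chr>    <chr>        <int>   <dbl>
#> 1 S00001    study001 CD              20    2.38
#> 2 S00002    study001 CD              20    2.54
#> 3 S00003    study001 CD              20    2.17

d <- differential_table(rel, "CD", "healthy")
dplyr::filter(d, direction != "unchanged")
#> # A tibble: 2 × 9
#>   taxon     rank  phylum condition_a condition_b  mean_a  mean_b  fold direction
#> 1 Bacteroi… fami… Bacte… CD          healthy     0.00308 0.00715  2.32 increase…
#> 2 Proteoba… fami… Prote… CD          healthy     0.0273  0.00730  3.74 increase…

net <- build_network(rel)
net
#> <coab_network> 20 families, 47 edges (r > 0.3, p < 1e-10), n = 600 samples
#>   intra-phylum edge fraction: 1

glance(random_null(net, n_reps = 1000, seed = 1))
#> # A tibble: 1 × 7
#>   observed_fraction expected_fraction_analytic mc_mean  mc_sd ...
#> 1                 1                      0.247   0.247 0.0551
```

Reading the numbers: the cohort plants a 2.4-fold Bacteroidetes decrease
and a 3.8-fold Proteobacteria increase in CD; at 200 samples per condition
the classifier recovers both directions with folds 2.32 and 3.74 (the small
shortfall from the planted values is compositional closure plus sampling
noise). The 20 families are simulated with strong within-phylum
co-abundance, so all 47 network edges are intra-phylum (fraction 1.0)
against a random-placement expectation of 0.247 — the observed network is
four times as phylum-assortative as chance.

The same chain runs from the shell:

```sh
exec/coabnet run --config pipeline.yaml   # simulate/aggregate/diversity/
                                          # diffabund/network/subnetwork also
                                          # available as subcommands
```

writing diversity, differential, edge-list, null-summary and GraphML
subnetwork files plus a plain-text summary, each stamped with the package
version, a config hash and the seed.

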