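---
title: "Methods: family co-abundance networks and taxonomic imbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family co-abundance networks and taxonomic imbalance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Gut microbiome surveys in inflammatory bowel disease (IBD) repeatedly find
that Crohn's disease (CD) and ulcerative colitis (UC) patients carry a less
diverse community than healthy controls, and that abundance shifts occur at
several taxonomic ranks. A natural follow-up question is relational: which
bacterial families tend to rise and fall *together* across many samples and
conditions, and where do the IBD-altered families sit inside that
co-abundance structure? `coabnet` implements the full chain needed to ask
this question of lineage-annotated count tables: rank aggregation,
diversity summaries, fold-change classification between conditions, and a
thresholded Pearson co-abundance network over bacterial families, with a
random-graph null for the network's phylum-level assortativity and
condition-specific subnetwork extraction.

Everything operates on one tidy currency: a long tibble with one row per
taxon × sample carrying the parsed lineage (`kingdom` … `genus`), sample
metadata (`sample_id`, `study_id`, `condition`) and the `count` (plus
`rel_abund` after normalisation). All user-facing functions take this table
first and return tibbles, so stages compose with the pipe.

# The model and its assumptions

## Normalisation

Counts are converted to per-sample proportions (`to_relative()`) before
correlation or fold-change work. Sequencing depth in multi-study gut
collections varies by more than an order of magnitude (the 16S data this
design targets ranged from 6,936 to 100,972 reads per sample), so raw counts
are not comparable across samples. Proportions are the simplest
depth-insensitive scale; a per-study stratified correlation
(`build_network(..., stratify_by_study = TRUE)`) is available where study
effects are a worry, but pooling is the default because the global network
is meant to describe co-abundance *across* conditions and cohorts. No
rarefying is applied by default.

## Co-abundance network

For every pair of eligible families, the Pearson correlation `r` of their
relative abundances across all samples is computed, with the two-sided
p-value of `t = r * sqrt((n - 2) / (1 - r^2))` under a t distribution with
`n - 2` degrees of freedom. This is the exact test under bivariate
normality; its behaviour when abundances are heavy-tailed is discussed under
limitations. A pair becomes an edge when **both** thresholds hold strictly:
`r > r_min` (default 0.3) and `p < p_max` (default 1e-10). Strictness
matters at the boundary: a pair at exactly `r = 0.3` is not connected.

Eligibility: a family must have a named (non-`unclassified`) phylum, be
present (count > 0) in at least `min_prevalence` samples (default 10), and
have a non-constant profile. The prevalence floor exists because
near-constant vectors make `r` numerically meaningless; constant vectors are
flagged `untestable` and can never form edges.

## Intra-phylum connectivity and its null

The headline statistic is the intra-phylum edge fraction: the share of
edges whose two endpoint families belong to the same phylum. Families from
one phylum often share metabolic requirements, so a co-abundance network
concentrated within phyla is biologically interpretable. To judge whether an
observed fraction is large, `random_null()` compares it with uniform random
placement of the same number of edges on the same labelled node set:

* analytically, `E[fraction] = sum_p C(n_p, 2) / C(N, 2)` over phyla `p`
  with `n_p` member nodes — independent of the edge count;
* by Monte-Carlo, drawing `n_edges` distinct pairs uniformly without
  replacement per replicate (seeded, reproducible).

Uniform placement ("same size" = same nodes and edge count) is the default
null; a degree-preserving rewiring null (`method = "rewire"`) is offered for
users who want to condition on the degree sequence as well.

## Fold-change classification

For each taxon at a chosen rank, the two condition means of relative
abundance are compared as `f = (mean_a + eps) / (mean_b + eps)` with
pseudocount `eps = 1e-6`; the reported fold is `max(f, 1/f) >= 1` and a
taxon is called changed only when the fold **strictly** exceeds the
threshold (default 1.5). The pseudocount bounds the fold for taxa absent in
one condition; as `eps -> 0` with positive means the fold converges to the
plain ratio. The arithmetic mean is the default central tendency (a median
option exists). No hypothesis testing or multiple-testing correction is
attached to this classification — it is a descriptive threshold rule, and
the direction classes feed the subnetwork colouring.

## Condition subnetworks

The disease-vs-healthy subnetwork keeps an edge of the global network iff
(a) at least one endpoint is among the most abundant families of either
contrasted condition (top `k = 15` by condition mean; the cut-off is a
package choice, exposed as `top_k`) and (b) at least one endpoint's fold
between the conditions strictly exceeds the threshold in either direction.
Retained nodes are annotated with their direction class (for colouring) and
their healthy-condition mean abundance (for node sizing). Annotations never
alter topology: subnetwork edges are always a subset of the global edges.

## Diversity

Richness is the count of taxa with positive counts. Shannon diversity is
`H = -sum(p_i * ln p_i)` in nats (natural log; `base = 2` available), so
`0 <= H <= ln(richness)` with equality at a uniform profile. Rarefaction
uses the analytic hypergeometric expectation
`E[S_d] = S - sum_i C(N - N_i, d) / C(N, d)`, evaluated with `lchoose` in
log space so totals in the 10^5 range do not overflow; Monte-Carlo
subsampling is retained only as a test oracle. The curve is nondecreasing
and concave in depth and equals observed richness at full depth.

# The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with known ground truth:

* **Hierarchy**: phyla each carrying a set of families
  (`phylum_famNN` labels).
* **Correlation blocks**: per sample, one latent N(0,1) factor per phylum;
  family log-abundance loads on it with weight `sqrt(block_rho)` (plus an
  optional global factor with weight `sqrt(between_rho)`), giving
  within-phylum log-scale correlation `block_rho` and between-phylum
  correlation `between_rho` (default 0).
* **Marginals**: baseline log-abundances default to an even gradient from 2
  to −2 (softmax shares spanning roughly a 50-fold range, as in real family
  tables); log-normal dispersion defaults to 1, a realistic
  order-of-magnitude spread for family abundances across people and
  cohorts.
* **Condition effects**: named fold multipliers applied on the log scale to
  chosen families before normalisation.
* **Counting**: proportions are sampled multinomially at a per-sample depth
  uniform in `depth_range` (default 6,936–100,972), which forces every
  downstream stage through normalisation. An ASV-level mode splits each
  family into 1–30 ASVs with Dirichlet(1) weights.

Ground truth (within-phylum family pairs as planted edges; per-condition
direction classes) is emitted with every dataset and can be written as TSVs
(`write_ground_truth()`).

`generate_ibd_cohort()` is a preset three-condition cohort (CD, UC,
healthy; 4 phyla, 20 families, `block_rho = 0.8`) with planted effects that
echo the imbalance magnitudes reported in IBD cohorts: one Bacteroidetes
family ×1/2.4 and one Proteobacteria family ×3.8 in CD, and a different
Proteobacteria family ×1/3.4 in UC.

**Closure and planted folds.** Because proportions must sum to one, a
planted fold `f` on a family with baseline share `q` realises an observed
relative-abundance fold of about `f / (1 + q (f - 1))`. The preset plants
its effects on families at roughly 1–2% baseline share, so the realised
folds sit within a few percent of the planted 2.4 / 3.8 / 3.4 — large
enough that the direction classes are recovered essentially always at
n = 200 samples per condition, the preset's default scale.

**What the generator does not emulate**: phylogenetic signal, ecological
interactions or dynamics, study-specific batch effects (each study is an
i.i.d. replicate of the same community), zero inflation beyond what the
multinomial induces, and read-level error. Passing tests therefore
demonstrate the pipeline's correctness and calibration under a log-normal
latent-factor world, not robustness to every artefact of real amplicon
data.

# Numerical and design choices

* **Sentinel ranks**: unknown or empty ranks parse to `"unclassified"`;
  such families (or families with unclassified phylum) are excluded from
  network construction by default because an assortativity statistic over a
  pooled pseudo-phylum is not interpretable. `include_unclassified = TRUE`
  restores them.
* **Taxon identity across studies** is label equality at the aggregated
  rank (trimmed, case-sensitive); no synonym resolution is attempted. When
  merged tables disagree on a label's lineage, the lexicographically first
  annotation wins, deterministically.
* **Canonical edges**: unordered pairs are stored once with
  lexicographically ordered endpoints and deterministically sorted output.
* **Ties** in the top-abundant ranking break lexicographically by label.
* **Aggregation** assigns each rank label the dominant (highest total
  count, ties lexicographic) parent lineage among its members.
* **Seeds**: every stochastic routine takes an explicit seed and uses it
  via a scoped RNG, so identical configurations are byte-identical across
  runs; pipeline outputs embed the seed, package version and a config hash
  in a header comment and deliberately omit timestamps.
* **p-value at |r| = 1** is defined as 0 (the t transform diverges).
* **Degenerate inputs**: empty tables, zero-total samples, all-zero count
  vectors, `depth` outside `[1, N]`, empty edge sets for the intra-phylum
  fraction, and `n_edges > C(N, 2)` for the null all raise informative
  errors rather than returning NaN.

Problem sizes in the test-suite: correlation oracles on 100 vector pairs
(n = 5–200); null calibration on 100 replicate datasets of 40 families ×
500 samples; planted-block recovery at 40 families × 1,000 samples; the
cohort preset at 200 samples per condition; rarefaction Monte-Carlo at
100,000 draws. These sizes keep the whole suite under a couple of minutes
on one core while leaving the statistical conclusions stable.

# Known limitations

* **Heavy tails inflate the Pearson test.** The t-transform p-value assumes
  bivariate normality. Relative abundances generated by a log-normal model
  with dispersion 1 are strongly leptokurtic, and at n = 500 the extreme
  tail of the null `r` distribution is orders of magnitude fatter than
  normal theory predicts: roughly a few pairs in 10^5 exceed r = 0.3 even
  for independent families, so occasional false-positive edges appear at
  that sample size. The package's null-calibration check measures exactly
  this. At the 10^4-sample scale of large public corpora the r > 0.3
  threshold dwarfs sampling noise and the issue disappears; at desk scale,
  users should treat isolated edges near the r threshold with suspicion or
  raise `r_min`.
* **Compositional closure.** Proportions induce spurious negative (and,
  through shared-denominator variance, weakly positive) correlations among
  families; no compositionality-aware correction (SparCC/SPIEC-EASI-style)
  is applied, matching the plain-Pearson design this package implements.
  Planted folds also realise slightly compressed, closure-distorted values
  (see above).
* **Jensen bias of mean proportions.** At large dispersion the empirical
  mean relative abundance of a small-share family exceeds the softmax of
  the baseline log-means (the ratio is convex in the denominator); the
  softmax is a good approximation of expected shares only at moderate
  dispersion (≲ 0.3). The generator's marginal check runs in that regime.
* **No batch correction.** Pooled correlations inherit any study-level
  composition differences as (co)variance; the stratified option averages
  per-study coefficients but computes its p-value at the pooled n, an
  approximation.
* **Descriptive fold classes.** The threshold rule carries no error-rate
  control; it is a screening and annotation device, not a differential
  abundance test.
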