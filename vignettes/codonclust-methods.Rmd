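---
title: "Methods: second-codon-position clustering and COG category bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: second-codon-position clustering and COG category bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonclust)
```

## The model

For a protein-coding gene read in frame, write f(X_n) for the frequency of
base X ∈ {A, C, G, T} at codon position n ∈ {1, 2, 3} among the gene's
codons. The second codon position is the most constrained one — it largely
decides the physicochemical class of the encoded amino acid (a T at
position 2 implies a hydrophobic residue, an A a hydrophilic one). In
prokaryotic genomes the per-gene pair (f(A2), f(T2)) is strongly bimodal:
most genes form a large cluster in which the two frequencies are similar,
while a minority — enriched for membrane and transport proteins — forms a
small cluster with much higher f(T2) and lower f(A2).

codonclust operationalizes this observation as a pipeline:

1. **Frequency profiling** (`genome_frequency_table()`): per gene, the 4×3
   matrix f(X_n) from non-overlapping in-frame triplets.
2. **Clustering** (`cluster_genome()`): K-means on the unscaled pair
   (f(A2), f(T2)), with the optimal K chosen by mean silhouette
   coefficient over K = 2–9; the K = 2 partition is designated SMALL (the
   minority, high-T2 side) and LARGE.
3. **Functional contrast** (`enrich_genome()`): a 2×26 chi-squared
   homogeneity test of COG category counts between the two clusters, plus
   per-category proportions F(P_small) = N(P_small)/N(small) and
   F(P_large) = N(P_large)/N(large) and an overrepresentation indicator
   that awards 1 to the cluster with the significantly higher proportion
   (both 0 when the difference is sub-threshold or tied).
4. **Cohort aggregation** (`run_cohort()`): significance-band summaries,
   cumulative per-category tallies, per-phylum overrepresentation ratios
   on tie-excluded denominators, and a cross-phylum consistency
   classification.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `drop_terminal_stop` | `FALSE` | whether a final TAA/TAG/TGA codon is excluded from counting; no exclusion rule is standard, so every complete codon counts by default and the switch exists for sensitivity checks |
| `min_genes` | 50 | genomes with fewer usable genes are rejected; silhouette analysis on tiny gene sets is noise |
| `k_range` | 2–9 | candidate cluster counts surveyed |
| `seed`, `n_restarts` | 20170326, 50 | K-means restart protocol; the module is a pure function of (points, seed, parameters) |
| `silhouette_subsample_cap` | `Inf` | optional cap on the points scored by silhouette (the O(n²) distance matrix dominates runtime on very large gene sets); an approximation switch, off by default |
| `threshold_mode`, `threshold` | `"relative"`, 0.05 | the overrepresentation rule: *relative* requires the difference to exceed 5% of the smaller proportion, *absolute* requires 5 percentage points |
| `category_policy` | `"first_letter"` | a gene annotated with several COG letters counts once (first letter), keeping column totals equal to gene totals; `"all_letters"` counts every letter |
| `min_genomes_per_phylum` | 10 | phyla with strictly more than this many genomes are retained in per-phylum ratios |

Numerical conventions: frequencies are exact ratios of integer counts; a
position whose denominator is zero (all ambiguous) reports zero
frequencies and is flagged; ties in optimal-K selection break toward the
smaller K (parsimony); an exact cluster-size tie designates the
higher-f(T2) centroid as SMALL, matching the biological definition of the
small cluster. Zero-total COG categories are dropped from the chi-squared
table with degrees of freedom reduced accordingly; no continuity
correction is applied, and expected counts below 5 produce a warning but
never alter the statistic.

### The two threshold readings

The 5% overrepresentation rule can be read two ways: as *5% of the lower
proportion* (relative) or as *a 5-percentage-point difference*
(absolute). Both are implemented; relative is the default and every
report names the mode used. The two differ materially: for a category
near 3% of the genome, the relative cutoff is ~0.0015 — smaller than
sampling noise at a few hundred annotated genes per cluster — so the
relative mode flags essentially any decided direction, while the absolute
mode flags only large shifts. Consumers comparing equal-probability
categories should use the absolute mode; the package's own calibration
test does.

## What the synthetic generator emulates — and what it does not

`simulate_genome()` draws genes from a two-component mixture
(`paper_like_components()`): a large component (weight 0.85) with
position-2 base probabilities centered at (f(A2), f(T2)) ≈ (0.32, 0.27)
and a small component (weight 0.15) at ≈ (0.22, 0.45). Gene lengths are
log-normal with median ~300 codons, so per-gene frequencies scatter
binomially (σ ≈ 0.02–0.03) around the component means — two well-separated
blobs, as in real prokaryotic genomes. Codons are i.i.d.; an in-frame
stop codon among non-final positions has its first base redrawn (every
stop starts with T), which perturbs the position-1 marginal only and
leaves positions 2 and 3 exactly at their specified distributions; the
final codon is forced to a stop.

Functionally, the small component doubles category P (inorganic ion
transport and metabolism), boosts U, V, S, G, and strongly depletes the
informational categories J, K, L (×0.15) — reflecting the observed
pattern in which the small high-T2 cluster carries almost no translation,
transcription or replication genes while the large cluster is enriched
for them (the large component boosts J ×1.8, K ×1.6, L ×1.6, F ×1.3,
H ×1.2). With these defaults a 2000-gene genome yields a decisively
significant 2×26 test (p ≪ 0.01) and indicator recovery for P and J in
essentially every seed, mirroring the near-universal significance seen in
real annotated prokaryotes.

What the generator does **not** model: codon usage bias within a
component (codons are position-wise independent), amino-acid level
constraints, operon or strand structure, phylogenetic correlation between
genomes (each genome is an independent draw), and annotation error. A
passing recovery test therefore shows the pipeline recovers planted
mixture structure of realistic effect size and geometry — it does not
validate the biological claim on real genomes, which requires real CDS
and COG inputs.

Seed handling: a cohort derives one child seed per genome from the master
seed and the genome's global index, so cohorts are reproducible and any
single genome can be regenerated in isolation.

## Design choices where the design was open

* **Feature space**: exactly (f(A2), f(T2)), unscaled — both coordinates
  already live on commensurate [0, 1] scales, so standardization would
  only distort the geometry.
* **K-means protocol**: `stats::kmeans` (Hartigan–Wong) under a
  deterministic restart loop with initial centers sampled among distinct
  points; 50 restarts and a fixed default seed give reproducibility and
  robustness to local minima. When K equals the number of distinct
  points the exact optimum (one cluster per distinct point, inertia 0)
  is returned directly. An empty-cluster restart is discarded rather
  than repaired.
* **Silhouette**: computed in-package from the full distance matrix
  because the degenerate contracts matter here — singleton clusters score
  0, and coincident points split across clusters (a = b = 0) also score
  0 rather than NaN. The implementation is cross-checked in the test
  suite against a naive O(n²) double loop and against
  `cluster::silhouette`.
* **Multi-letter annotations**: `first_letter` by default so the 2×26
  table's column totals equal gene counts and the test remains a genuine
  homogeneity test; `all_letters` is available when per-letter counting
  is wanted.
* **Unannotated genes** are clustered but excluded from all enrichment
  denominators.
* **Strictly-more-than-10** genomes per phylum, per the conventional
  retention rule; the boundary (exactly 10) is excluded.
* **Cross-phylum consistency**: a category is consistent-large
  (consistent-small) when the large (small) ratio wins in every retained
  phylum where the category is decided; categories decided nowhere are
  reported as mixed with `n_phyla_decided = 0` so the caller can tell
  the two situations apart.

## Problem sizes used in the test suite

The suite exercises the pipeline at deliberately modest scales chosen to
keep the statistical claims meaningful: oracle checks run at n ≤ 25
points (silhouette) and n ≤ 10 (exhaustive K-means partitioning);
optimal-K recovery uses 20 genomes of 600 genes; enrichment recovery uses
20 genomes of 2000 genes (~1800 annotated); the type-I calibration uses
2000 replicates of 500 + 500 annotated genes. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch under
a caller-supplied seed.

## Known limitations

* The silhouette subsample cap trades exactness for speed on very large
  gene sets and is off by default; when on, scores are approximations.
* The chi-squared p-value relies on the asymptotic distribution; rare
  categories routinely have expected counts below 5 (the package warns).
  With ~26 columns and hundreds of genes per cluster the test is mildly
  conservative (empirical type-I ≈ 4.5% at the 5% level).
* Per-genome p-values are reported raw; no multiple-testing correction
  across genomes is applied — cohort summaries count raw per-genome
  verdicts.
* The relative threshold mode is extremely permissive for rare
  categories (see above); interpret per-category indicators for rare
  letters with care.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
sim <- simulate_genome("demo", n_genes = 800, seed = 1)
report <- run_genome(sim, genome_annotation(sim),
                     config = pipeline_config(n_restarts = 10))
glance(report$clustering)
glance(report$enrichment)
autoplot(report$clustering)
```
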