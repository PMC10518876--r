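# cstmove

Community-state typing and longitudinal cluster-movement analysis for nasal
microbiome cohorts.

## The problem

Longitudinal 16S amplicon studies of the upper respiratory tract — for
example cohorts of frail older adults sampled before, during and after
influenza-like illness (ILI) — produce ASV count tables whose samples fall
into a small number of recurring compositional configurations (community
state types, CSTs), most of them dominated by a single genus such as
*Corynebacterium*, *Moraxella*, *Staphylococcus* or *Dolosigranulum*. The
scientific questions are then: which CSTs exist, which metadata variables
(if any) are associated with community composition, and how stable is each
individual's CST over time — in particular, does an ILI episode knock a
subject into a different CST, and does that change persist?

`cstmove` implements that analysis end-to-end for R users working at the
ASV-table level:

* **QC filters** — removal of samples with `< 10^3` 16S rRNA gene copies by
  qPCR and of samples below a minimum read depth.
* **Diversity** — Shannon index H = −Σ pᵢ ln pᵢ; rarefaction without
  replacement; Bray–Curtis dissimilarity BC(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ) on
  rarefied counts; the centred log-ratio (CLR) transform and Aitchison
  distance (Euclidean on CLR) on unrarefied counts; classical PCoA with
  uncorrected negative eigenvalues.
* **Community-state typing** — complete-linkage hierarchical clustering of
  the distance matrix, with the number of clusters k chosen to maximise the
  mean silhouette width s(i) = (b(i)−a(i))/max(a(i),b(i)); singleton
  clusters are excluded; each cluster is labelled with its dominant taxon
  (a genus exceeding 35 % relative abundance in more than 70 % of member
  samples) or `"mixed"`.
* **Permutation statistics** — one-factor PERMANOVA (pseudo-F on the
  partitioned squared-distance matrix, with R²), ANOSIM (rank-based R) and
  PERMDISP (distances to group centroids in PCoA space, residual
  permutation), all with the (1+b)/(1+m) p-value convention, seedable
  permutations and an exhaustive-enumeration mode for small designs;
  Brown–Forsythe spread tests; Yates-corrected 2×2 and Pearson r×c
  chi-squared tests; Bonferroni thresholds; per-taxon Spearman correlations
  with bacterial load.
* **Metadata screening** — the three inclusion rules (≤15 % missingness;
  ≥10 % minority share for binaries; discrete levels must each carry >3 %
  of observations, otherwise the level is dropped) plus pairwise
  association testing between covariates and per-variable PERMANOVA.
* **Movement analysis** — per-subject trajectories over PRE → ILI → POST
  samples and the four-category classification: (1) same cluster
  throughout; (2) moved at ILI but returned; (3) moved at ILI and did not
  return; (4) moved only after ILI. Mover frequencies are compared between
  groups by Yates chi-squared, and cluster-to-cluster transition counts are
  emitted as matrices.
* **A synthetic cohort generator** — Dirichlet-multinomial samples drawn
  from nine compositional archetypes (eight dominant-taxon, one mixed
  high-diversity), individualised trajectories with planted movement
  categories, arm-level effects and exact ground truth, used throughout the
  test suite.

## Worked example

```r
library(cstmove)

sim <- simulate_cohort(cohort_config(n_subjects = 40, seed = 2024))
res <- run_full_pipeline(sim$dataset,
                         pipeline_config(seed = 2024, n_permutations = 199,
                                         k_range = 2:12))

res$assignment
#> cluster_assignment: 83 samples in 9 clusters (0 excluded)

res$cluster_summary[, c("cluster_id", "n", "label", "median_shannon")]
#>   cluster_id  n           label median_shannon
#> 1          1 15       Moraxella      0.8475531
#> 2          2  5           mixed      3.6886213
#> 3          3 13 Corynebacterium      0.9251181
#> 4          4 10       Moraxella      1.0457671
#> 5          5 10  Staphylococcus      0.8322422
#> 6          6 10  Dolosigranulum      1.2663132
#> 7          7  5       Moraxella      1.1311557
#> 8          8  8 Corynebacterium      1.0173734
#> 9          9  7 Corynebacterium      1.3676568

res$cluster_tests$anosim
#> ANOSIM R = 1.0000, p = 0.005 (199 permutations)

res$frequency_tests$ili$percent_moved
#>    FALSE     TRUE
#> 45.83333 77.77778
```

The pipeline recovers the nine simulated archetypes (k = 9 by silhouette),
labels each cluster by its dominant genus — the mixed cluster is the most
diverse (median Shannon 3.69 versus ≤1.37 elsewhere) — and confirms the
clusters are compositionally distinct (ANOSIM R = 1). Among subjects who
experienced ILI, 77.8 % moved between clusters versus 45.8 % of those who
did not, reflecting the configured loss of temporal stability under ILI
(at n = 40 subjects this difference is not yet significant; the frequency
test p-value is in `res$frequency_tests$ili$test`).

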