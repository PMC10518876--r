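---
title: "Community-state typing and cluster movement: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-state typing and cluster movement: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `cstmove`, the
parameters that matter, the numerical conventions, and the reasoning for
the choices that were genuinely open. It is the companion to the function
reference; nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis model

The package treats a longitudinal amplicon cohort as a feature table of
ASV read counts (samples × ASVs), per-sample metadata (subject, timepoint
class PRE/ILI/POST, trial arm, typed clinical covariates) and a 16S qPCR
copy-number table. The analysis proceeds:

1. **Quality filters.** Samples with fewer than `min_copies = 1e3` 16S
   copies are removed (strictly `<`, so a sample at exactly the threshold
   is kept); samples below a minimum read depth are removed. The read
   floor has no privileged default in the science — `filter_min_reads`
   takes it as an argument, and the pipeline default of 1268 reads matches
   the rarefaction depth so that no sample is silently dropped at the
   rarefaction step.
2. **Diversity and distances.** Shannon diversity uses natural logs (the
   vegan convention; the base is an argument). Bray–Curtis dissimilarities
   are computed on counts rarefied to a common depth; Aitchison distances
   are computed on unrarefied counts, because the CLR transform is
   scale-invariant for zero-free compositions and rarefaction would only
   discard reads. Rarefaction is a single multivariate-hypergeometric draw
   per sample (no averaging across draws), deterministic under its seed.
3. **Community-state typing.** Complete-linkage hierarchical clustering of
   the Bray–Curtis matrix; k is selected by maximising the mean silhouette
   width over `k_range` (default 2..20); singleton clusters are excluded
   and the remaining clusters renumbered; clusters are labelled by the
   dominant-taxon rule (>35 % relative abundance in >70 % of member
   samples, both strict) at genus level, falling back to `"mixed"`.
4. **Statistics.** Cluster validity via PERMANOVA, ANOSIM and PERMDISP on
   the same distance matrix; metadata inclusion screening and pairwise
   association tests; per-variable PERMANOVA with R².
5. **Movement.** Per-subject trajectories ordered by collection order;
   when a subject has several ILI samples, the first is the one used for
   classification. ILI subjects with PRE, ILI and POST samples are
   classified into categories 1–4; non-ILI subjects with PRE and POST get
   a moved/stayed flag only, because the categories are defined relative
   to an ILI sample. Anyone missing a required timepoint is
   UNCLASSIFIABLE and excluded from frequency tests — this is also why
   arm comparisons run on fewer subjects than report ILI.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `min_copies` | 1e3 | 16S copies per sample; low-biomass exclusion |
| `min_reads` | 1268 (pipeline) | reads; library-size floor |
| rarefaction depth | min library size | reads; common depth for Bray–Curtis |
| CLR `pseudocount` | 1 | added to every count before logs |
| `k_range` | 2..20 | candidate cluster numbers |
| `abundance_cut` | 0.35 | dominant-taxon relative abundance, strict `>` |
| `prevalence_cut` | 0.70 | within-cluster prevalence, strict `>` |
| `n_permutations` | 999 | permutation tests; p floor 1/1000 |
| `alpha` | 0.05 | screening / flagging level |

## Numerical conventions

* **Permutation p-values** follow `(1 + b) / (1 + m)` where `b` counts
  permuted statistics ≥ the observed (with a 1e-10 slack for floating-point
  ties). `exhaustive = TRUE` enumerates every relabelling instead and
  reports the exact fraction ≥ observed, including the identity; with two
  tight pairs in two groups of two this gives exactly 1/3.
* **PERMANOVA** uses the squared-distance partition SS_T = Σᵢ<ⱼ d²ᵢⱼ/N,
  SS_W = Σ groups (within-group Σ d²)/n_g, F = (SS_A/(a−1))/(SS_W/(N−a)),
  R² = SS_A/SS_T. One factor only.
* **ANOSIM** ranks all N(N−1)/2 dissimilarities with average ties;
  R = (mean between-rank − mean within-rank)/(M/2).
* **PERMDISP** keeps the negative PCoA axes: a sample's distance to its
  group centroid is √max(0, d₊² − d₋²), combining real and imaginary
  parts; the test permutes least-squares residuals of the one-way model.
  Centroids (not spatial medians), no bias adjustment.
* **PCoA** reports negative eigenvalues uncorrected (no Lingoes/Cailliez);
  coordinates exist only for positive axes and `proportion_explained` is
  relative to the positive-eigenvalue sum.
* **2×2 chi-squared** applies the Yates continuity correction by default:
  on the mover/stayer table (24,4 / 8,6) the corrected statistic is 2.77
  (p = 0.096) where the uncorrected would be 4.2 (p ≈ 0.040); the
  corrected convention is the one consistent with published comparisons of
  this kind. Tables larger than 2×2 are never corrected.
* **Brown–Forsythe** is the default spread test (absolute deviations from
  group *medians*); classic mean-centred Levene is behind
  `center = "mean"`.
* **Silhouette** is computed directly on the distance matrix by default;
  a `space = "pcoa"` mode computes it on Euclidean distances over the
  positive PCoA axes instead. Either input space is defensible when both
  the distances and their ordination are in play; the distance matrix is
  the determinate choice (no axis-count decision) and is therefore the
  default. Members of singleton clusters get silhouette width 0, the
  common convention. Ties in k-selection go to the smallest k (parsimony).
* **Degenerate inputs** fail loudly: zero-sum samples, all-equal distance
  matrices, empty clusters, filters that would remove every sample, and
  tables with zero margins all raise errors naming the offender.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. It
emulates the post-denoising state of a nasal 16S dataset with a
Dirichlet-multinomial model: each of nine archetypes has a mean
composition over a 60-ASV panel and a shared concentration (default 150);
a sample is a multinomial draw at a log-normal depth (median ≈ 20 000
reads, floored at 1268) from a Dirichlet-perturbed composition. The
Dirichlet-multinomial is the minimal model that reproduces overdispersed
compositions with a dominant taxon.

Eight archetypes have a dominant ASV at mean proportion 0.5–0.8 with the
remaining mass decaying geometrically over a few background taxa (keeping
their expected Shannon low); three are *Corynebacterium*-dominated and
three *Moraxella*-dominated, each by a distinct ASV, plus one
*Staphylococcus* and one *Dolosigranulum* archetype. The ninth archetype
is mixed: no mean proportion reaches 0.2 and its expected Shannon index
exceeds all others.

Movement is planted, not emergent: each subject's true category is drawn
first and archetypes consistent with it second, so ground truth is exact
and the classifier can be held to 100 % recovery. A mover's destination
archetype is uniform over the other archetypes, mirroring the observed
unpredictability of transitions. Default rates encode the study
conditions: ILI attack probability 0.34; mover probability 0.487 without
ILI; 0.857 (placebo) and 0.571 (active) with ILI; 12.5 % of ILI movers
return to their PRE cluster (category 2), which follows from the reported
87.5 % of movers not returning. The category-4 share among movers
(movement only after ILI) is not reported anywhere we can derive it from;
the default of 0.25 is an assumption chosen once to keep all three mover
categories populated at realistic cohort sizes. Second ILI samples occur
with probability 7/51 and POST dropout with probability 23/150. qPCR
copies are log-normal (meanlog = log 3e4, sdlog = 2), putting ~4 % of
samples under the 1e3-copy filter so the low-load path is exercised.
Covariates include one deliberately associated pair (care-home site and a
site-shifted cytokine) plus variables engineered to trip each screening
rule.

What the generator does **not** emulate: sequencing error, chimeras,
primer/extraction bias, contamination, taxonomic misassignment, unequal
cluster prevalences, within-archetype temporal drift, or covariate effects
on composition. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct under its own model assumptions — not that
real nasal data will cluster this cleanly. On real data the silhouette
curve is flatter, cluster sizes are skewed, and label support values sit
closer to the thresholds.

## Problem sizes used by the test suite

The suite favours many small, exact checks over few large, loose ones.
Exhaustive-enumeration equivalence runs on designs up to n = 8 (≤ 70
distinct assignments, scored independently by vegan). Null calibration
uses 500 replicates at n = 16 with 199 permutations for PERMANOVA and
ANOSIM, 1000 replicates for Brown–Forsythe, and 500 for the association
screen, asserting rejection rates in [0.03, 0.07] at α = 0.05. Parameter
recovery pools 25 simulated cohorts of 150 subjects; cluster recovery runs
25 seeds of 108 samples over the nine archetypes at concentration 1000
(the well-separated regime) and requires k = 9 in ≥ 90 % of seeds with
dominant-taxon labels matching archetype truth.

## Known limitations

* One-factor PERMANOVA only; no sequential multi-factor or stratified
  permutation designs.
* No phylogenetic (UniFrac) metrics and no tree handling.
* The CLR pseudocount (+1) is a pragmatic zero-replacement; count-zero
  multiplicative replacement and other imputations are out of scope.
* Differential-abundance testing is deliberately excluded; established
  tools exist and slot in downstream of the cluster assignments.
* Movement categories require all three timepoints for ILI subjects;
  partially sampled subjects contribute nothing to frequency tests, which
  can bias comparisons if dropout correlates with instability.
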