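---
title: "Models and methods behind crosscortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crosscortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosscortex)
```

crosscortex compares the cellular and laminar organization of the primary
visual cortex between two species — a eutherian rodent ("mouse" preset) and a
marsupial ("opossum" preset) — across three modalities: single-nucleus
RNA-seq, spatial transcriptomics of cortical pseudocolumns, and
immunofluorescence histology. This vignette explains the models, the tunable
parameters, and the design choices; the README shows a worked example.

## The synthetic data generator

No deposited animal data ships with the package. Instead, a generator
produces datasets with the statistical structure the analysis assumes, plus a
ground-truth record, so every downstream stage can be tested by parameter
recovery. The generative model is deliberately minimal:

* **Taxonomy.** Three classes (glutamatergic, GABAergic, non-neuronal).
  Glutamatergic cells include four intratelencephalic (IT) subclasses — one
  per modeled layer (2/3, 4, 5, 6) — plus two projection subclasses; the
  GABAergic class holds the five interneuron subclasses Pvalb, Sst, Vip,
  Lamp5 and Frem1. The presets pin the GABAergic composition to the values
  the atlas comparison should recover: Pvalb is 50% of GABAergic cells in
  the opossum preset and 35% in the mouse preset.
* **IT continuum.** Each IT cell's latent log-expression is a convex mixture
  of four archetype programs with Dirichlet-distributed weights. The mouse
  preset concentrates weight near the vertices (base concentration 0.2,
  vertex bonus 6); the opossum preset spreads weight across the face spanned
  by the first three archetypes (base 0.8 on A-C, 0.2 on D, vertex bonus 2).
  This is the vertex-peaked vs. face-spread contrast the archetype analyses
  target.
* **Counts.** Gene rates are the softplus of the latent mixture, normalized
  per cell and scaled by a log-normal library size (meanlog log 6000 for
  mouse, log 4000 for opossum — the shallower-coverage species); counts are
  negative binomial with a shared dispersion (size 2). The full-scale QC
  thresholds then apply to the synthetic atlases unchanged. No ambient RNA,
  doublets or batch chemistry are simulated, so passing recovery tests says
  nothing about robustness to those artifacts in real data.
* **Space.** In the spatial modality each subclass draws its depth from a
  truncated normal law (means spanning a 1,200 µm column), and IT archetype
  weights are drawn from a depth-conditioned Dirichlet so transcriptomic
  identity covaries with laminar position. Coordinates are emitted in
  platform units at 2 units per micron.
* **Histology.** Fields carry an additive vertical background gradient plus
  Gaussian pixel noise; PV centroids follow a Poisson process with
  layer-specific intensities (opossum density 1.2 times mouse); perineuronal
  rings (5–15 µm annuli) are painted either at PV centroids (mouse preset)
  or at random deep-layer sites away from PV cells (opossum preset).

Noise defaults (latent sd 0.3, NB size 2, pixel noise 0.05) are calibration
choices — neither platform's noise model is published — fixed once so that
subclass structure is recoverable but not trivial. Gene programs are drawn
under a separate `program_seed` per species, so atlases generated under
different seeds share their "biology" and can serve as reference/query pairs
for label transfer.

## Preprocessing and embedding

QC keeps cells with detected genes strictly between 700 and 6,500 and fewer
than 40,000 UMIs, then genes detected in more than eight surviving cells;
the spatial variant keeps cells with at least 50 genes and 100 UMIs and
converts chip units to microns. Normalization is log counts-per-10k.
Variable genes are ranked by variance over a loess mean–variance trend (a
plain variance ranking when the mean range is degenerate). This
normalization replaces the variance-stabilizing transform used by common
toolkits: downstream operations only require a normalization whose gene
centering and scaling can be stored for out-of-sample projection, which the
PCA embedding records explicitly. PCA can balance labels by fitting loadings
on a per-subclass downsample (default: the smallest subclass size) and
projecting all cells, so abundant subclasses do not dominate the axes.
Clustering builds an exact kNN graph, reweights it by shared-neighbour
Jaccard similarity with the conventional 1/15 pruning, and runs Leiden at
resolution 1 under a fixed seed.

## Cross-species operations

Cross-species work is restricted to one-to-one orthologs. Full anchor-based
integration is out of scope; `integrate_embed()` implements a fully
specified replacement — per-dataset z-scoring, joint PCA, and a single
global translation per dataset equal to the mean displacement across mutual
nearest neighbour pairs toward the largest dataset. This removes a global
batch offset while leaving within-dataset geometry untouched, which is all
the downstream statistics require, and it is deterministic.

Balanced label transfer runs 100 iterations by default: each iteration draws
at most 100 cells per subclass from a depleting pool (reset when exhausted,
so every reference cell is used before any is reused), fits a PCA on the
draw, projects the query, and votes among the 30 nearest reference cells
with inverse-distance weights; probabilities are averaged over iterations
and ties break lexicographically. The voting rule is the minimal faithful
mechanism for "nearest-neighbour label transfer in 30 dimensions"; the
dims/cap/iteration structure follows the published procedure.

The cluster-overlap statistic between subclasses i and j is
$O(i,j) = \sum_c \min(n_{ic}/n_i,\; n_{jc}/n_j)$ over integrated clusters:
1 exactly when the two subclasses distribute identically over clusters, 0
when they never co-cluster.

## Archetypal geometry

`pcha_fit()` implements principal convex hull analysis: minimize
$\lVert X^\top - X^\top C S\rVert^2$ with the columns of $C$ (cells ×
vertices) non-negative summing to within $[1-\delta, 1+\delta]$ and the
columns of $S$ on the simplex. Optimization alternates projected-gradient
updates with per-block adaptive step sizes and a backtracking line search;
gradients are first projected onto the simplex tangent space (subtracting
each column's component along the current point) so the clamp-renormalize
projection preserves descent — the SSE path is asserted non-increasing on
every fit. Initialization is furthest-sum seeding. Explained variance is
defined as $1 - \mathrm{SSE}/\mathrm{TSS}$ with TSS the total squared
deviation from the data mean (conventions differ between archetypal-analysis
implementations, so the package fixes this one).

Vertex-count selection fits candidates 2–10 (best of 5 restarts plus one
warm start that extends the previous candidate's solution by the
worst-reconstructed point — which makes the explained-variance profile
provably non-decreasing) and picks the candidate maximizing the
perpendicular distance to the chord joining the first and last profile
points, ties to the smallest count. The delta default is 0 for tetrahedron
analyses and 0.1 for the spatial triangle fit, the convention this kind
of triangle analysis uses.

The continuum-vs-discrete test is a documented stand-in for a published
shuffling procedure whose exact statistic is not publicly specified: the
statistic is the kernel-density trough along the centroid-difference axis
between the two subclass medians, relative to the smaller median-point
density (1 = continuum, 0 = gap); the null independently permutes each
gene's values within each subclass, preserving marginals while destroying
gene–gene covariance. Its outputs are not claimed to reproduce the original
procedure's figures.

## Laminar statistics

Subpial density profiles are Gaussian kernel densities of normalized depth
with reflection at 0 and 1 (bandwidth 0.05 of the column); Gini confinement
uses 20 equal-width depth bins (no standard bin structure exists; 20 bins
resolves the five laminar bands without starving counts),
$\mathrm{Gini} = \sum_{ij} |c_i - c_j| / (2B\sum c)$, so 0 is depth-uniform
and $(B-1)/B$ is single-bin confinement. The below/above density ratio
normalizes counts by the extent of each region — a density, matching the
figure's wording — with the split at the reference subclass's median depth.
Depth–axis associations use partial Spearman correlations controlling for
the alternate vertex distance, with significance from 10,000 permutations of
depth only (the distance pair stays intact).

Multi-round spatial label assignment uses agreement thresholds 100/100/75%
(class) or 100/75/50% (subclass) among 50 cross-modal neighbours, with the
reference downsampled to the query size in round 1 only; later rounds use
the full reference (re-downsampling there would only discard information). Cells assigned in earlier rounds are removed and never
relabeled; re-integration happens each round (the removal only has an effect
if the embedding changes). Plurality ties leave a cell unassigned for that
round.

## Histology metrics

Background is removed by grayscale morphological opening with a 50 µm disk
and the image normalized to the 99.5th percentile of in-mask corrected
signal (with a fallback to the maximum when the percentile lands on zero
for very sparse foregrounds). Arc-length profiles project centroids and
pixels onto the nearest pial-polyline point and bin by cumulative arc
length; density is cells per mm² of in-mask bin area. Perineuronal-net
enrichment per PV cell is the median corrected intensity in the 5–15 µm
annulus minus the median in a 25–50 µm local background annulus — the
background annulus radii have no canonical value and are exposed as
parameters. The depth-matched null samples, per PV cell, 10 points whose
depth is drawn from the observed PV depths with ±5 µm jitter and whose
arc-length position is uniform, excluding points within 15 µm of any PV
centroid; cells or null points whose outer annulus exits the mask are
censored symmetrically.

## Inference

Group comparisons use one-way ANOVA followed by two-sided Tukey HSD and
Bonferroni multiplication across families (a family = one figure panel),
capped at 1. The rank-sum test is exact (permutation distribution) for
tie-free samples up to a combined size of 50 and the tie-corrected normal
approximation otherwise; complete separation at sizes 3 and 4 gives the
exact two-sided p = 2/35 ≈ 0.0571. Differential expression filters on
log2 fold change of linear normalized means > 0.75, detection fraction in
the first group > 0.25, and unadjusted p < 0.05 (a Benjamini–Hochberg
adjusted column is emitted but not used for filtering).

## Problem sizes and determinism

The recovery experiments run at desk scale, chosen once as the package's
study conditions: 20 seeded IT continua of 2,000 cells × 300 genes for
vertex-count recovery; 10,000-cell atlases (2,000 genes, 500 variable genes,
30 embedding dimensions) with 5 transfer iterations and 5 seeds per species
for composition recovery; paired
2 × 1.2 mm histology fields over 5 seeds for the density contrast; 500
replicates of 199-permutation tests for type-I calibration. Every stochastic
step takes an explicit seed, and generators restore the session RNG state,
so identical configuration yields bit-identical output.

## Known limitations

UMI downsampling resamples without replacement (multivariate hypergeometric),
which preserves expected proportions and guarantees no entry grows — the
natural reading of "proportional reduction" that is also closed under the
original counts. The synthetic continuum is low-dimensional by construction;
elbow selection on data without archetypal structure will still return some
candidate. The MNN shift corrects only a global translation per dataset;
nonlinear batch distortions are out of scope. Histology fields use a straight
pial surface by default; the projection machinery supports curved polylines
but the generator does not emulate cortical curvature.
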