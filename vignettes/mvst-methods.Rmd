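---
title: "Multi-view spatial-domain detection: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view spatial-domain detection: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MVST)
```

## The model in brief

MVST treats spatial-domain identification as multi-view deep embedded
clustering. Spots are nodes; three k-NN graphs encode three notions of
similarity — physical proximity, expression similarity in a reduced
PCA space, and similarity of handcrafted histology-image features. A
graph convolutional autoencoder per view compresses the shared node
attribute matrix $X$ (the PCA expression features) into a view
embedding $Z_m$, the embeddings are fused convexly
($Z = \sum_m \beta_m Z_m$), and a Student-t soft assignment $Q$ around
$k$ centroids, together with its sharpened target $P$
($p_{ij} \propto q_{ij}^2 / f_j$, $f_j = \sum_i q_{ij}$), drives
self-training. The composite loss is

$$L = \underbrace{\sum_m \lVert X - X_m' \rVert_F^2}_{L_e}
    + \underbrace{\sum_{i \ne j} \lVert Z_i - Z_j \rVert_F^2}_{L_{gr}}
    + \underbrace{\sum_m \rho_m \lVert Q_m - P \rVert_F^2}_{L_{pd}}.$$

Two assumptions carry the method: spatially adjacent spots tend to
share expression programs, and histology texture/colour co-varies with
domain identity. Tissues violating either (e.g. salt-and-pepper
infiltration, stain artefacts) will blur the corresponding view;
`beta` exists precisely so users can down-weight an uninformative
view.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `k` (all graphs) | 10 | neighbours per spot before union symmetrisation; matches the hexagonal grid's natural neighbourhood scale |
| `nHVG` | 2000 | highly variable genes kept (dispersion ranking in 20 mean bins) |
| `nPCs` | 1000 | PCA components forming $X$; clipped to $n_{\text{spots}}-1$ on small sections |
| `nPCsGraph` | 50 | expression-graph search space: the *leading 50 columns* of the already-computed PCA. For a nested PCA of the same matrix this is numerically identical to recomputing a 50-component PCA, so no second decomposition is run |
| `minCells` | 5 | a gene must be detected in at least this many spots |
| `patchPx` | 50 px | histology patch side; auto mode uses the spot diameter when Space Ranger scale factors are present |
| `hiddenDims`, `dz` | 256, 64 | encoder widths (input → 256 → 64), decoder mirrored; ReLU hidden, linear bottleneck |
| `beta` | equal | view-fusion weights; renormalised with a warning if they do not sum to 1 |
| `alpha` | 1 | Student-t degrees of freedom, the conventional choice for t-kernel clustering |
| `rho` | 1 per view | weight of the distribution-consistency term |
| `lrPretrain` / `lrJoint` | 1e-3 / 1e-4 | Adam learning rates of the two phases |
| `epochsPretrain` / `epochsJoint` | 200 / 200 | fixed epoch budgets; no early stopping by default (`earlyStop` offers a <0.1 % label-change rule between P refreshes) |
| `pRefresh` | 20 | epochs between target-distribution refreshes; P is a constant between refreshes (no gradient flows through it) |
| `attention` | TRUE | learned row-stochastic propagation; FALSE restores the plain normalised convolution |

## Design choices where the design was open

**Attention integration.** The symmetric normalisation
$D^{-1/2}G'D^{-1/2}$ and the attention coefficients $Y$ are both
propagation operators; we use $Y$ (masked to the self-looped edge
pattern, row-softmaxed, hence row-stochastic) *in place of* the
normalised adjacency when attention is on. With the attention vectors
at their zero initialisation, $Y$ is exactly uniform over each
neighbour set — row-normalised mean aggregation — so attention starts
as a benign reparametrisation and learns departures from it. The
per-node scores attach $t_s$ to the emitting node (row) and $t_r$ to
the neighbour (column).

**Bottleneck as view embedding.** The final (linear) encoder layer
output serves directly as $Z_m$; no separate projection head is
stacked on top. This keeps the autoencoder symmetric and the parameter
count minimal. Decoder weights are independent of the encoder (not
tied transposes).

**Cluster-frequency index.** The target distribution uses *column*
sums $f_j = \sum_i q_{ij}$ (cluster frequencies) — the standard deep
embedded clustering construction. An empty cluster is excluded with a
warning rather than producing NaNs.

**Geometric-consistency pair convention.** $L_{gr}$ sums over
*ordered* view pairs, so each unordered pair is counted twice; the
factor is constant in the optimisation and the tests assert it
explicitly (two views at Frobenius distance 2 contribute 8).

**Centroid initialisation.** After pretraining, centroids come from
k-means on the fused embedding, seeded by deterministic farthest-point
(maximin) selection followed by Lloyd iterations. Random-restart
k-means would sample rows and thus break a property we consider part
of the method's contract: permuting spot order permutes labels
identically. Maximin seeding is order-invariant up to exact distance
ties, which are measure-zero for continuous embeddings.

**PCA.** Exact LAPACK SVD with a deterministic sign convention (the
largest-magnitude loading of each component is made positive). At the
scales this package targets the exact decomposition is fast, and it
removes a seed dependence that a randomised solver would introduce.

**k-NN search.** Exact all-pairs distances with stable
ascending-index tie-breaks. Ball-tree style accelerators return the
same edge set by definition; at $n \lesssim 10^4$ spots the exact
search is not the bottleneck. Symmetrisation is by union: an edge
survives if either endpoint ranks the other in its top k.

**GLCM conventions** (the statistics pin down the family but not the
parameters): 64 gray levels, offset distance 1, angles
0°/45°/90°/135°, symmetric and normalised matrix, statistics averaged
over angles, entropy $-\sum p \log_2 p$ over nonzero cells,
correlation defined as 1 when a marginal variance vanishes (constant
patch). CLAHE runs per patch on a 2 × 2 tile grid (patches are small;
odd dimensions are trimmed by one pixel), and is skipped for patches
under 8 px.

**Dropout and noise corruption.** Dropout is an independent Bernoulli
mask per matrix entry; ratios above 0.7 are rejected because the
matrix becomes too sparse to support the feature pipeline. Poisson
noise is *additive* (counts never decrease), with rate
$\lambda = \text{level} \times \text{grand mean}$ by default and a
per-gene mode behind `meanMode`.

## What the synthetic generator emulates — and what it does not

`simulateSection()` produces the three inputs with known truth: a
hexagonal-offset grid, negative-binomial counts
(variance $\mu + \mu^2 \cdot 0.5$ at the default dispersion) whose
domains up-regulate disjoint 50-gene marker sets five-fold over a
log-normal baseline (`baseMean = 2`), and a stain-like image whose
domains differ by an RGB tint (offsets of magnitude 40 on 0–255
channels, pixel noise sd 10). These defaults are the package's
standing study conditions: well-separated expression programs (a
nearest-centroid classifier on normalised counts already classifies
the planted domains essentially perfectly — the recovery checks
validate the machinery end to end rather than pose a hard inference
problem), and an image channel about as informative as a clean
stain.

The generator does **not** emulate: spot-to-spot library-size
gradients, spatial bleed/swapping artefacts, realistic H&E morphology
(nuclei, texture at the cell scale), partial-tissue spots, or
annotation noise. Passing the recovery tests therefore demonstrates
correctness of the machinery and sane optimisation dynamics — not
performance on real tissue, where domain boundaries are softer and
views can disagree.

## Numerical notes

- All randomness in a fit flows from `config$seed`; two fits with the
  same seed are bit-identical, and label CSVs written by `runMVST()`
  are byte-identical across repeats.
- Ties: k-NN ties break by ascending spot index; `assignLabels()`
  breaks probability ties toward the lower cluster index; both are
  deterministic.
- Degenerate inputs: an edgeless graph makes the propagation operator
  the identity (every spot keeps a self-loop); a node with no
  neighbours gets attention weight 1 on its self-loop; zero-IQR
  feature columns scale by 1 with a warning; all-zero count matrices
  and single-cluster ARI comparisons raise documented errors or
  conventions (ARI 1 for two single-cluster partitions).
- Divergence (a non-finite loss component) aborts with the phase,
  epoch and component named.
- Gradients of every trainable block — GCN layers, attention softmax
  and sigmoid, Student-t assignment, centroids — are analytic and are
  verified against central finite differences in the suite.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline on the
default 900-spot section with 300 HVGs, 50 PCA components, encoder
32 → 16, and 50 + 50 epochs — sizes chosen so a complete fit takes
seconds while every code path (three views, attention, both phases,
corruption operators) is exercised; the unit oracles use ≤ 10-node
instances where hand computation is exact. Defaults in the API remain
the full-scale settings described above.

## Known limitations

- Visium-style spot data only; no support for single-cell-resolution
  platforms, multi-section integration or batch effects.
- Handcrafted image features: no learned CNN embedding, registration
  or stain normalisation — heavily artefacted images will degrade the
  histology view.
- Full-batch training keeps the whole propagation in memory; sections
  beyond ~10⁵ spots would need mini-batching that is not implemented.
- The Louvain domain-count convenience depends on graph resolution and
  should be treated as a starting point, not an inference.
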