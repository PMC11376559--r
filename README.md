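# MVST

Unsupervised spatial-domain identification for spot-based spatial
transcriptomics (10X Visium) from three complementary views of the
tissue: spatial proximity, gene-expression similarity, and
histology-image similarity.

## The problem

A Visium slide measures gene expression at thousands of barcoded spots
laid out on a hexagonal grid over a stained tissue section. A *spatial
domain* is a contiguous tissue region — a cortical layer, a tumour
nest — whose spots share both an expression program and a histological
appearance. Clustering expression alone fragments such regions;
clustering coordinates alone ignores biology. MVST couples the two,
together with the image, for users who want domain labels per spot with
no manual annotation.

## The model

Three symmetric binary k-nearest-neighbour graphs are built over the
same spots (k = 10 each):

- **spatial view** `A` — Euclidean distance between spot coordinates;
- **expression view** `B` — distance in a 50-dimensional PCA expression
  space (after gene filtering, median-library normalisation, log1p,
  top-2000 HVG selection and scaling);
- **histology view** `C` — distance between robust-scaled per-spot image
  features: six gray-level co-occurrence (GLCM) texture statistics of
  the CLAHE-equalised grayscale patch (contrast, dissimilarity,
  homogeneity, ASM, entropy, correlation) plus mean R, G, B intensity.

Each view *m* feeds a graph convolutional autoencoder. An encoder layer
computes

    H^(l) = sigma( P_m H^(l-1) W^(l) ),

where the propagation operator `P_m` is the symmetrically normalised
self-looped adjacency `D^(-1/2) (G_m + I) D^(-1/2)`, or — with attention
enabled (the default) — a learned row-stochastic matrix `Y`:
per-node scores `s = H W t_s` (own node) and `r = H W t_r` (neighbour)
give edge scores `U_ij = sigmoid(s_i + r_j)`, soft-maxed over each
node's neighbour set. The bottleneck output is the view embedding
`Z_m`; a mirrored decoder reconstructs the input features.

The view embeddings fuse into a consistent clustering embedding
`Z = beta_1 Z_1 + beta_2 Z_2 + beta_3 Z_3` (`sum beta = 1`). A
Student-t kernel around k cluster centroids gives the soft assignment

    q_ij ∝ (1 + ||z_i − mu_j||² / alpha)^(−(alpha+1)/2),

and its sharpened, frequency-corrected transform
`p_ij ∝ q_ij² / f_j` is the self-training target. Training minimises

    L = L_e + L_gr + L_pd
      = Σ_m ||X − X'_m||²_F  +  Σ_{i≠j} ||Z_i − Z_j||²_F
        +  Σ_m rho_m ||Q_m − P||²_F

in two phases: reconstruction-only pretraining, then joint training
with P refreshed on a fixed interval. The hard label of spot *i* is
`argmax_j p_ij`. Agreement with reference annotations is scored with
the adjusted Rand index (ARI).

The autoencoder, attention, losses and the Adam training loop are
implemented in base R with hand-derived analytic gradients (checked
against finite differences in the test suite).

## Worked example

Every stage runs on a bundled synthetic generator, so no downloads are
needed. The default section is a 30 × 30 hexagonal grid with three
layered domains, 500 genes (50 markers per domain at fold-change 5) and
a domain-tinted fake stain image:

```r
library(MVST)

section  <- simulateSection(seed = 1)
section
#> SpatialSection: 900 spots x 500 genes
#>   image: 540 x 630
#>   planted domains: 3

features <- preprocessSection(section, nHVG = 300, nPCs = 50)
graphs <- list(buildSpatialGraph(section),
               buildExpressionGraph(features),
               buildHistologyGraph(
                 extractHistologyFeatures(section, patchPx = 20)))
graphs[[1]]
#> ViewGraph <spatial>: 900 spots, 4910 undirected edges (k = 10)

cfg <- mvstConfig(hiddenDims = 32, dz = 16,
                  epochsPretrain = 50, epochsJoint = 50, seed = 1)
fit <- fitMVST(features, graphs, nDomains = 3, config = cfg)
fit$assignment
#> DomainAssignment: 900 spots, 3 domains
#> domain
#>   1   2   3
#> 300 300 300

adjustedRandIndex(section$domain, domainLabels(fit$assignment))
#> [1] 1
```

The three planted 300-spot bands are recovered exactly (ARI 1). On real
Space Ranger output, replace the generator with
`section <- readVisium("path/to/outs")` and keep the defaults
(`nHVG = 2000`, `nPCs = 1000`, `mvstConfig()`); `nDomains = NULL`
estimates the domain count by Louvain clustering. `runMVST()` wraps the
whole pipeline and writes labels, embeddings, the loss trace and a
config echo to an output directory; `inst/cli/mvst.R` exposes the same
as shell subcommands (`run`, `simulate`, `corrupt`, `evaluate`,
`ablate`).

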