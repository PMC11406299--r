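---
title: "Stability-driven pattern discovery and atlas linking: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-driven pattern discovery and atlas linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the factorization model and its assumptions, the stability criterion used
for model selection, the spatial statistics and atlas queries built on top,
the parameters that matter and why their defaults are what they are, what
the synthetic generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The data model

The input is a stack of per-gene 3D volumes on a shared grid
(`expression_tensor`), a voxel mask selecting the tissue of interest, and
optionally a labeled atlas with an ontology table. All analysis happens on
the flattened voxel-by-gene matrix `X` (v × n) whose row order is fixed by
the mask's index map; `assemble_matrix()` and `unmask()` are exact inverses
on the mask, so volumes and matrices can be exchanged freely. Volumes are
grid-native: NRRD and NIfTI headers are honoured only for dimensions (and
voxel spacings when present), never for orientation, because every stage
operates on a fixed common lattice.

Missing voxels — ISH energy grids typically lack on the order of 10% of
voxels — are imputed per gene with a spatial k-nearest-neighbour rule: the
unweighted mean of the k = 6 nearest observed voxels in Euclidean voxel
coordinates. Six neighbours is the natural first shell on an isotropic
grid (the face neighbours). The imputer is deliberately per-gene and
purely spatial: it preserves each gene's own smoothness, needs no
cross-gene training, never touches observed values, and is bounded by each
gene's observed range because it averages observed values. Distance ties
are broken by ascending linear voxel index so the result is deterministic.
Whether imputation should precede or follow masking is not decidable from
first principles; the package imputes on the full grid and masks
afterwards, which uses out-of-mask context where it exists and is the more
conservative order.

## Factorization

The core model is non-negative matrix factorization,
minimising `||X − D A||²_F` subject to `D, A ≥ 0`. Non-negativity matches
the physics of expression energy (intensities add, they do not cancel) and
yields parts-based patterns; principal component analysis is provided as
the natural linear baseline (`method = "pca"`), with each component's sign
pinned so its score skewness is non-negative — PCA is sign-invariant, and
an unpinned sign would contaminate every downstream stability and
similarity comparison.

The NMF solver is hierarchical alternating least squares (block coordinate
descent): each dictionary column and coefficient row has a closed-form
non-negative update, every update is non-increasing in the loss (the
recorded `loss_trace` is asserted monotone in the tests), and iteration
stops when the loss decrease falls below `tol = 1e-4` of the initial loss
or after `max_iter = 200` sweeps — the conventional defaults for
coordinate-descent NMF at this scale. Initialization is deterministic
NNDSVD (the SVD-based non-negative decomposition), with zero entries
replaced by the matrix mean so coordinate descent cannot lock a component
at zero. Determinism here is a design commitment, not a convenience: the
stability analysis below attributes *all* variation across refits to data
perturbation, which requires that refitting the same matrix twice is
bit-identical. The `seed` argument of `fit_patterns()` therefore only
labels provenance; randomness enters exclusively through bootstrap
resampling upstream. A sanity check in the test suite confirms that the
instability of repeated non-bootstrap refits is numerically zero
(≤ 1e-9).

## Stability analysis and the choice of K

For each candidate K, the gene columns of `X` are resampled with
replacement (size n) `n_runs` times and each resample is factorized. The
bootstrap axis is genes, not voxels: dictionaries live in voxel space, and
resampling voxels would change the very space in which two dictionaries
are compared. Dictionaries from different runs are compared with the
column cross-correlation matrix; Pearson correlation is used because its
normalization delivers the required invariance to positive column scaling
(a cosine-similarity mode is available via `mode = "cosine"`). Permutation
invariance is handled either by Hungarian assignment (exact one-to-one
matching maximizing total correlation, solved by the O(K³) potentials
algorithm and verified against brute-force enumeration over all K!
permutations in the tests) or by the Amari-type error built from row and
column maxima. The instability score γ(K) is the mean pairwise
dissimilarity over all unordered run pairs; `select_K()` takes the argmin,
ties to the smaller K (prefer the simpler model).

Run-level seeds derive as `seed + (K index − 1) · n_runs + run`, so every
(K, run) pair draws an independent bootstrap sample and runs can execute
in any order with identical results.

## Spatial statistics

Global Moran's I summarizes the spatial coherence of a pattern:
`I = (v/S0) · Σ w_ij z_i z_j / Σ z_i²` with mean-centred in-mask values
and binary, symmetric, non-row-standardized weights over face-adjacent
in-mask voxel pairs (6-connectivity; 18 and 26 available). Face adjacency
is the minimal canonical neighbourhood on a voxel lattice; because no
weight convention is universal, the implementation is checked against an
independent dense-matrix evaluation of the same formula rather than
against a remembered value, and results on real data may shift slightly
under other conventions. The statistic is invariant to positive affine
rescaling and to negation of the field, and its permutation expectation
−1/(v−1) is verified by Monte-Carlo in the tests. Dice similarity of
binarized patterns (threshold at the 0.9 in-mask quantile by default,
`binarize_pp()`) is provided as the overlap counterpart.

## Atlas queries and entity linking

Two regions are spatially contiguous when the one-step binary dilation of
one overlaps the other. For a single dilation step this is exactly voxel
contact under the structuring element's connectivity, so the adjacency
list is built by label-pair scanning over shifted lattices — equivalent
to, and tested against, brute-force voxel-contact scanning. The default
structuring element is the full 3×3×3 cube (26-connectivity), the most
permissive single-step choice; triples {i, j, l} extend pairs {i, j}
whenever the dilated third region overlaps at least one member.

Entity linking seeks, for each pattern, the single region or contiguous
pair/triple whose normalized (0/1) union mask maximizes Pearson
correlation with the pattern over in-mask voxels. Because atlas regions
are disjoint, union counts and union sums decompose into per-region terms,
giving a closed-form correlation per combination; the exhaustive search is
therefore linear in the adjacency-list size and exact. Combinations of
order above 3 are deliberately out of scope (the search space grows
exponentially). Mask normalization — dividing each label-valued region
mask by its label — makes every combination a plain indicator before
union, so large label values carry no weight.

## Markers, networks, predictability

Each gene is assigned to its highest-coefficient pattern, and its
importance is the share `r_j = a_kj / Σ_k a_kj` of total coefficient mass
(the denominator sums over patterns, making r a share in [0, 1]). sGCN
nodes are a pattern's assigned genes with importance in the global top
0.25% — a global cutoff so the node count per pattern scales with the
gene universe — and edges are the top 5% of pairwise Pearson correlations
between reconstructed gene volumes, with the edge count
`ceiling(edge_quantile × n_pairs)` and all orderings resolved on sorted
gene names so the network is independent of input order. The
"represented patterns per gene" count uses a relative share threshold of
0.01; this threshold is genuinely underdetermined and is exposed in the
configuration rather than fixed in code. Region predictability fits an
L2-regularized logistic regression (glmnet, α = 0, fixed λ = 0.01,
standardized features) of region membership on pattern values and reports
the training AUC by the Mann–Whitney rank statistic, against a null of
random same-size pattern subsets.

## The synthetic generator

`make_atlas()` partitions an ellipsoidal "brain" (background shell of
zeros) into Voronoi cells grown from uniformly random seed voxels and
groups them into coarse parents (about one per four regions, by k-means on
seed coordinates), emulating the blocky, hierarchical structure of
anatomical parcellations. `make_expression()` plants `K_true` patterns,
each the Gaussian-smoothed indicator (kernel SD 1 voxel, radius 3 SD) of a
contiguous combination of 1–3 regions chosen greedily so regions are not
reused; smoothing uses normalized (mask-aware) convolution — dividing the
smoothed indicator by the smoothed brain indicator — because real
expression energy does not attenuate where the tissue ends at the brain
boundary. Marker genes load on a single pattern each; all other genes
load on at least two patterns with no share above 0.85, so pattern
exclusivity is what identifies markers. Loadings are Dirichlet shares
times a gamma scale; noise is additive Gaussian truncated at zero
(expression energy is continuous and non-negative, so a truncated Gaussian
is more faithful than Poisson counts); missing voxels are uniform per
gene at the requested fraction.

What the generator does *not* emulate: realistic anatomy (region shapes
are convex-ish Voronoi cells), intensity heterogeneity across genes,
spatially structured missingness (real ISH misses whole sections),
registration error, and within-region expression gradients. Passing tests
on this generator therefore demonstrate correctness of the algorithms
under the model's own assumptions — planted-factor recovery, exact
adjacency, exact assignment — not performance on real atlas data, where
patterns are not exactly low-rank and regions are not exactly homogeneous.

## Problem sizes and numerical choices

The standard desk-scale study used by the test suite and the acceptance
script is a 20 × 16 × 14 grid (≈ 1,600 in-brain voxels), 12 regions, 200
genes, 5 planted patterns, noise SD 0.05, and 10% missing voxels, with
stability scans over K ∈ 2..9 at 20 bootstrap runs; unit tests use smaller
variants (≈ 500–750 voxels, 3 planted patterns). These sizes keep every
property — K recovery across 10 seeds, matched-correlation to truth,
adjacency-oracle agreement on 50 random atlases — computable in minutes
while remaining large enough that bootstrap instability separates the
planted K clearly.

Degenerate inputs are handled by sentinel, not by guess: zero-variance
fields, constant gene columns, all-zero genes, and empty mask pairs
return `NA` with a warning wherever a correlation or statistic is
undefined; all-zero dictionary columns correlate 0 with everything (with
a warning) so a degenerate fit cannot masquerade as a stable one.
Hungarian assignment ties, quantile ties in the sGCN edge cut, equal
coefficient maxima, and equal instabilities all break deterministically
(lowest index, sorted gene names, smaller K).

## Known limitations

* The smoothing of planted indicator patterns bounds their correlation
  with crisp region masks: combinations of small, high-curvature regions
  saturate below ≈ 0.93 even when linking recovers the combination
  exactly. Linking accuracy should be judged by recovery, with the
  correlation as a secondary magnitude.
* Bootstrap resampling of genes assumes genes are exchangeable; strongly
  duplicated gene families effectively up-weight their shared pattern.
* The solver finds a local optimum of a non-convex objective; the
  deterministic initialization makes this reproducible but not provably
  global. The stability criterion mitigates, and partially conceals, this:
  a consistently-found local optimum is indistinguishable from a global
  one.
* Moran's I and adjacency depend on lattice conventions (connectivity,
  row standardization); all are configurable, and cross-convention
  comparisons should re-run rather than re-scale.
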