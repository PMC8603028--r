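---
title: "Measuring and analysing 3D root crown architecture with rootcrown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and analysing 3D root crown architecture with rootcrown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcrown)
```

## The measurement problem

Field-excavated maize root crowns keep their three-dimensional
architecture because the upper root system is lignified. Imaged by X-ray
computed tomography in air, a crown becomes a high-contrast grayscale
volume from which architecture can be measured without the occlusion that
limits 2D photography. `rootcrown` implements the full chain: volume
ingestion, segmentation, skeletonization, a registered 71-trait panel,
and the downstream statistics used in multi-environment field studies —
outlier rules, per-trait ANOVA under false-discovery-rate control,
variance components and broad-sense heritability, trait–pulling-force
association, and multivariate classification by genotype, environment and
developmental time.

All geometry is expressed in physical units through the voxel size
(micrometres per voxel edge; bench-top crown scans typically resolve
100–120 um). Volumes are stored as R arrays indexed `[x, y, z]` with
slice `z = 1` at the top of the crown (the stem end); RAW files are
headerless with a YAML sidecar carrying the grid dimensions, voxel size,
bit depth and byte order.

## Segmentation

Washed crowns imaged in air separate from background by a single global
threshold, either fixed or chosen by Otsu's criterion; the chosen level is
recorded in the result's provenance, and degenerate outcomes (empty or
all-foreground masks) are flagged rather than silently returned so batch
runs can quarantine a sample. Speckle is removed by 26-connectivity
component filtering with a deterministic tie-break (lowest `(z, y, x)`
seed voxel) when only the largest component is kept.

## Skeleton and skeleton traits

The mask is thinned to a one-voxel curve skeleton by sequential deletion
of simple points under the (26, 6) adjacency pair — object voxels
26-connected, background 6-connected — in six directional subiterations
with endpoint protection. This preserves the topology of the mask exactly
(components and loops survive), which is why the synthetic-data generator
below takes care to produce crowns without spurious handles.

Three numerical corrections matter for accurate lengths and are applied
by default:

* **Spur pruning.** Thinning a thick organ leaves short surface spurs;
  branches ending in a tip that are shorter than twice the local radius
  at their junction are removed (configurable, logged).
* **Path smoothing.** Summing raw inter-voxel steps (1, √2, √3)
  overestimates oblique curve lengths by up to ~15% (staircase wiggle).
  Edge paths are smoothed with a 5-voxel moving average, endpoints
  anchored, before measuring.
* **Tip extension.** Thinning erodes tube ends by about one local radius
  before the endpoint condition engages; each terminal edge is extended
  by the distance-transform radius at its tip. For capsule-shaped organs
  this recovers the true centreline length.

Local radii come from an exact Euclidean distance transform. Junction
voxels within a Chebyshev radius of 2 collapse into one "bifurcating
cluster", since a single thick bifurcation thins to several adjacent
junction voxels. On analytic fixtures the skeleton length of a 100-voxel
cylinder is recovered within 1%, and on simulated crowns the total length
agrees with the generator ledger to a few percent (mean ~2%, worst ~8%
over a 15-seed survey).

## The 71-trait panel

The registry (`trait_registry()`, shipped as
`inst/extdata/trait_registry.csv`) is the single source of truth for
names, units and column order: 19 classical skeleton/shape traits, 2
box-counting fractal dimensions, 21 vertical-distribution statistics,
20 per-slab solidity bins and 9 radial compactness shells. Choices the
names alone do not pin down are resolved as follows and should be read as
this package's contract:

* **Surface area** uses a weighted local 2×2×2 configuration estimator
  rather than an isosurface mesh. On binary masks, meshing the raw mask
  misestimates both smooth and flat surfaces (digitized sphere ~+8%,
  sharp-edged 10-voxel cube ~−6%), and pre-smoothing destroys small flat
  fixtures entirely. Instead every boundary cell contributes a calibrated
  patch area: the flat axis-aligned interface class is fixed at exactly
  1 voxel², the ambiguous 2-adjacent-corner class is split by local
  context into sharp-edge chains versus 45° sheets, and the remaining
  weights are fit by nonnegative least squares over digitized balls,
  cubes, boxes, cylinders and ellipsoids with analytic areas
  (`scripts/calibrate-surface-weights.R` regenerates them). Validation:
  sphere r20 −0.6%, cube 10³ −1.6%, cylinder r5 +4.6%. Thin tubes at
  r ≲ 3 remain the least accurate regime.
* **Convex hulls** are taken over voxel *cell corners* (centres ± ½), not
  centres, so Solidity = Volume / ConvexHullVolume can never exceed 1.
* **HorEqDiameter** is the diameter of the circle whose area equals the
  maximal horizontal-slice convex area — an interpretation of "root crown
  width" chosen from the name; Elongation is Depth over that diameter.
* **Fractal dimension** is box counting on the side (along-y) or top
  (along-z) binary projection, box sizes 1..2^⌊log₂ min(dim)⌋, grid
  anchored at the bounding-box corner; a single anchor keeps the trait
  deterministic (offset averaging is available by flag). Plane-filling
  projections measure 2.0 exactly, lines 1.0, and a depth-5 Sierpinski
  carpet 1.862 against the self-similarity value 1.893.
* **Vertical profiles** split the occupied depth into 20 equal slabs
  (slab 1 at the stem). Per-slab biomass, hull area and solidity are all
  computed and returned, but only the solidity bins are registry traits;
  the biomass and hull-area profiles enter the panel through their seven
  distribution statistics each. With 19 legacy traits, 2 fractal
  dimensions, 3 × 7 distribution statistics, 20 solidity bins and 9
  radial shells the panel totals exactly 71; the slab and shell counts
  are configurable, but non-default values are flagged because the
  registry columns assume the defaults.
* **Distribution statistics** treat a profile as a discrete distribution
  over slab indices (`p = v / Σv`): mean, SD, skewness and kurtosis as
  standardized moments, energy `Σp²`, entropy `−Σp log₂ p` in bits, and
  smoothness `1 − 1/(1 + var(p))` with the variance over the normalized
  values — the texture-descriptor convention, so a uniform profile has
  smoothness 0.
* **DensityS** partitions radial distance from the vertical axis through
  the horizontal centroid into 9 equal shells up to the outermost root
  voxel; shell k reports the root fraction of its bounding-cylinder
  volume over the occupied depth. Nine shells make the 71-trait census
  exact and are consistent with the S1..S9 naming.

## The synthetic crown generator

`generate_crown()` exists to give the imaging pipeline an oracle: every
generated crown carries an analytic ledger (total centreline length, tip
counts, per-root polylines) computed before rasterization. The geometry
emulates a maize crown at bench-CT scale: a vertical stem stub with
first-order roots inserted phyllotactically down its length (consecutive
bases ~150° apart in azimuth), emerging 40–72° from vertical and bending
downward under a weak pull, tapering from 3 voxels radius, with optional
Poisson-placed laterals. Tube tips are trimmed by one tip radius so the
hemispherical cap ends exactly at the polyline end, keeping the ledger
equal to the rasterized extent.

Two design constraints keep the ledger verifiable. Roots are grown
collision-free against each other (a candidate polyline that would touch
another tube is regrown with fresh curvature noise), because fused tubes
make "total length" ill-defined; and bases sit on the stem axis, because
a collar of mutually touching tubes around the stem creates handles whose
loops a topology-preserving skeleton must keep. Real crowns *do* fuse at
the crown mass — passing tests on these synthetic crowns therefore
validates the measurement chain on clean architectures, not the
behaviour of the skeleton on heavily fused or soil-contaminated organs.
The generator also does not emulate scanner physics: no beam hardening,
noise texture, or partial-volume gradients (the segmentation tests add
Gaussian intensity noise separately).

`simulate_phenotypes()` is the statistics-side generator: independent
Gaussian genotype, environment, interaction and residual effects at
chosen variances, with unbalanced replication supported. Its
`true_h2` attribute evaluates the entry-mean heritability
`H² = σ²G / (σ²G + σ²GxE/e + σ²res/re)` at the simulation variances,
where `e` is the number of environments and `re` the mean replicate
count per genotype pooled over environments (r × e in a balanced
design, so σ²G = 2, σ²GxE = σ²res = 1 at 2 environments × 3 replicates
gives H² = 0.75).

## Statistical workflow

The univariate chain mirrors standard multi-environment phenomics
practice: PCA score-distance flagging of gross outliers (|score| > 4 SD
on PC1 or PC2; flagged, never silently dropped), Tukey fences at
1.5 IQR with type-7 quartiles per trait, per-trait linear models tested
with Type-II sums of squares (`car::Anova`; Type III by flag),
Benjamini–Hochberg adjustment across traits *within each factor family*,
Mann–Whitney tests, Spearman correlations against an anchor such as root
pulling force, and OLS with adjusted R². Variance components come from
REML (`lme4`) with genotype, environment and their interaction as random
intercepts; negative estimates are truncated at zero by the fitting
constraint, and heritability can be stratified by time point for repeated
harvests.

Classification follows the two standard designs of multi-environment root phenomics. PCA-LDA scans every
three-genotype combination: traits standardized (without it, large-unit
traits dominate the components), principal components retained to 90%
cumulative variance, LDA scored by leave-one-out cross-validation, and
per-trait importance aggregated as |loading| × |discriminant weight|.
The procedure is deterministic. Binary random-forest classification
(environment or time point) grid-searches mtry 1–20 × ntree
{500, 1000, 2500, 5000} under 10-fold cross-validation repeated three
times, then refits the best model with proximity and both permutation
and Gini importance, and embeds 1 − proximity in 2D by nonmetric
multidimensional scaling (reported with its stress). Tests and the
acceptance script shrink the grid (a single mtry/ntree cell) and use
simulated tables of 126–200 samples — null accuracies do not depend on
the grid, and the full grid is a parameter away.

Null calibrations are estimated the way a permutation test would:
because all C(9,3) genotype triples share the same 126 samples, a single
label permutation fluctuates by several accuracy points, so the null is
averaged over five permutations (observed ~0.33 against the 1/3
expectation; random-forest nulls sit at ~0.50).

## Degenerate inputs and numerical conventions

Empty masks are rejected; all-background segmentations are flagged;
coplanar point sets yield a missing hull; projections under 4×4 yield a
missing fractal dimension; crowns shallower than the slab count yield a
flagged missing profile; constant traits yield undefined correlations and
zero variance components. Ties in "keep largest component" break by seed
order; box-counting uses a single deterministic anchor; all generators
restore the caller's RNG state and are bit-reproducible under a fixed
seed.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use a 10³ cube, an r = 20
ball, r = 5–10 cylinders, a 243² Sierpinski carpet, three default crowns
(~25k root voxels each), 100 simulated traits at 50 genotypes × 2
environments × 3 replicates for heritability recovery, 126-sample
9-genotype tables for PCA-LDA and 200-sample tables for random forests —
sizes at which the Monte-Carlo error of each check is several times
smaller than its tolerance.

## Known limitations

Surface area for tubes thinner than ~3 voxels is underestimated; skeleton
length on heavily fused crown masses counts shared segments once (the
physical object, not the sum of constituent roots); the box-counting
dimension of finite fixtures sits slightly below the self-similarity
limit; REML variance components at 2 environments estimate σ²GxE with
few degrees of freedom, so single-trait H² is noisy and only trait-panel
averages are tightly calibrated; and the PCA-LDA importance aggregate is
one of several defensible conventions — rankings, not magnitudes, should
be interpreted.
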