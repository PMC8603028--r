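# rootcrown

3D phenotyping of field-excavated maize root crowns imaged by X-ray
computed tomography, together with the statistical workflow used in
multi-environment root architecture studies.

Root crowns pulled from the field keep their 3D shape because the upper
root system is lignified. Scanned in air by bench-top CT, each crown
becomes a grayscale voxel volume; `rootcrown` turns that volume into a
registered panel of 71 architectural traits and analyses the resulting
trait tables:

* **Imaging chain** — headerless RAW / slice-stack ingestion with a YAML
  metadata sidecar (voxel size in µm drives all unit conversions), global
  thresholding (fixed or Otsu) with provenance, 26-connectivity
  component cleanup, topology-preserving 3D thinning to a curve skeleton
  lifted to an attributed graph (tips, junctions, edge lengths, local
  radii from an exact Euclidean distance transform), and point-cloud /
  slice exports.
* **Trait panel** — 19 classical skeleton and shape traits (total root
  length, tips, bifurcating clusters, average radius, specific root
  length, volume, surface area, convex hull, solidity, depth, width,
  elongation, slice-wise root counts), 2 box-counting fractal
  dimensions, 21 vertical-distribution statistics (mean, SD, skewness,
  kurtosis, energy, entropy, smoothness of the biomass, convex-hull and
  solidity depth profiles), 20 per-slab solidity bins and 9 radial
  compactness shells.
* **Statistics** — PCA and Tukey-fence outlier rules, per-trait ANOVA
  (Type-II SS) with Benjamini–Hochberg control, Mann–Whitney tests,
  Spearman trait–pulling-force correlation, OLS with adjusted R², REML
  variance components and entry-mean broad-sense heritability
  `H² = σ²G / (σ²G + σ²GxE/e + σ²res/re)`, PCA-LDA genotype
  classification over all three-genotype combinations (components to 90%
  variance, leave-one-out CV), and random-forest environment/time
  classification with grid search, proximity and NMDS.
* **Synthetic data** — a seeded root-crown generator with an analytic
  ground-truth ledger (the oracle for the imaging chain) and a phenotype
  simulator with controlled genotype / environment / G×E / residual
  variances (the oracle for the statistics).

## Worked example

Generate a synthetic crown, measure it, and compare with the generator's
analytic ledger:

```r
library(rootcrown)

cr <- generate_crown(crown_spec(seed = 42))
cr$volume
#> <binary_volume>
#> <volume_meta> 123 x 132 x 141 voxels, 110.0 um/voxel, 8-bit little-endian
#>   17678 root voxels (0.772% of grid)

tr <- extract_traits(cr$volume, sample_id = "crown_42")
round(unlist(tr[1, c("TotalRootLength", "NumberOfTips",
  "NumberBifurcatingClusters", "AvgRootRadius", "Volume", "SurfaceArea",
  "Solidity", "Depth", "FractalDimensionSide", "MaxRootCount")]), 3)
#>           TotalRootLength              NumberOfTips NumberBifurcatingClusters
#>                    12.835                    14.000                    12.000
#>             AvgRootRadius                    Volume               SurfaceArea
#>                     0.218                     0.024                     1.730
#>                  Solidity                     Depth      FractalDimensionSide
#>                     0.031                     1.430                     1.540
#>              MaxRootCount
#>                    13.000

cr$truth$total_length_cm
#> [1] 12.705
```

The measured total root length (12.84 cm) agrees with the ledger
(12.71 cm) to ~1%; the crown's 12 first-order roots plus the two stem
ends give the 14 tips; solidity near 0.03 is typical for a sparse,
spreading crown. Units follow the trait registry (`trait_registry()`):
lengths in cm, radius in mm, volume in cm³, surface in cm².

Simulated phenotypes recover their designed heritability:

```r
tab <- simulate_phenotypes(pheno_sim_spec(n_genotypes = 50, n_traits = 5,
                                          seed = 1))
round(heritability_table(tab)$h2, 3)
#> [1] 0.724 0.876 0.756 0.561 0.718
attr(tab, "true_h2")
#> [1] 0.75
```

Real scans enter through `read_raw_volume()` / `read_slice_stack()` and
the batch driver `run_pipeline()` (or the `exec/rootcrown` command-line
front end: `raw2img`, `segment`, `traits`, `simulate-crown`,
`simulate-phenotypes`, `stats`, `classify`); deposited trait tables enter
through `read_trait_table()` and `analyze_trait_table()`.

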