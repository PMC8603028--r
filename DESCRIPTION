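Package: rootcrown
Title: 3D Root Crown Phenotyping from X-Ray Computed Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end phenotyping of excavated maize root crowns imaged by
    X-ray computed tomography. Reads headerless RAW volumes and grayscale
    slice stacks, segments root from air, thins the mask to a medial curve
    skeleton lifted to an attributed graph, and extracts a registered panel
    of 71 architectural traits: classical skeleton and shape traits (total
    root length, tips, bifurcating clusters, radius, convex hull, solidity,
    depth, width, fractal dimension) plus vertical-distribution and radial
    compactness traits. Includes a seeded synthetic root-crown generator with
    analytic ground truth, a phenotype simulator with controlled
    genotype/environment/GxE variance, and the downstream statistical
    workflow: PCA and Tukey-fence outlier rules, per-trait ANOVA with
    Benjamini-Hochberg control, Mann-Whitney tests, Spearman correlation,
    variance components by REML with broad-sense heritability, PCA-LDA
    genotype classification over all three-genotype combinations, and
    random-forest environment/time classification with proximity and NMDS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    jsonlite,
    tiff,
    png,
    MASS,
    car,
    lme4,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
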