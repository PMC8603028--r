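test_that("crown generation is bit-reproducible under a fixed seed", {
  a <- generate_crown(crown_spec(seed = 5))
  b <- generate_crown(crown_spec(seed = 5))
  expect_identical(a$volume$mask, b$volume$mask)
  expect_identical(a$truth$total_length_vx, b$truth$total_length_vx)
  c2 <- generate_crown(crown_spec(seed = 6))
  expect_false(identical(a$volume$mask, c2$volume$mask))
})

test_that("the ground-truth ledger is consistent with the rasterized crown", {
  cr <- generate_crown(crown_spec(seed = 5))
  expect_equal(cr$truth$n_voxels, sum(cr$volume$mask))
  expect_equal(cr$truth$n_first_order, 12)
  expect_equal(length(cr$truth$root_lengths_vx), length(cr$truth$polylines))
  # polylines live inside the auto-sized grid
  pts <- do.call(rbind, cr$truth$polylines)
  expect_true(all(pts >= 0 & sweep(pts, 2, dim(cr$volume$mask), "<=")))
})

test_that("a single straight tube measures its ledger length", {
  cr <- generate_crown(crown_spec(n_first_order_roots = 1,
                                  curvature_sd_deg = 0, taper_rate = 0,
                                  root_length_vx = c(90, 90),
                                  insertion_angle_deg = c(35, 35),
                                  trunk_length_vx = 0, seed = 3))
  sk <- skeletonize(cr$volume)
  expect_equal(skeleton_traits(sk, cr$volume)$NumberOfTips, 2)
  expect_rel_error(sum(sk$edges$length_vx), cr$truth$total_length_vx, 0.05)
})

test_that("laterals add tips and ledger length", {
  cr <- generate_crown(crown_spec(laterals_per_cm = 1.2, seed = 9))
  expect_gt(cr$truth$n_laterals, 0)
  expect_equal(cr$truth$n_tips,
               cr$truth$n_first_order + cr$truth$n_laterals + 2)
  sk <- skeletonize(cr$volume)
  st <- skeleton_traits(sk, cr$volume)
  expect_lte(abs(st$NumberOfTips - cr$truth$n_tips), 3)
})

test_that("phenotype simulation honours its variance structure", {
  # no interaction or residual noise: replicates within a cell identical
  det <- simulate_phenotypes(pheno_sim_spec(n_genotypes = 6, replicates = 3,
                                            sigma2_GxE = 0, sigma2_res = 0,
                                            seed = 2))
  spread <- tapply(det$trait_01,
                   interaction(det$genotype, det$environment),
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))

  # law of large numbers: genotype-mean variance approaches sigma2_G
  big <- simulate_phenotypes(pheno_sim_spec(n_genotypes = 300,
                                            replicates = 4, sigma2_G = 2,
                                            sigma2_E = 0.5, sigma2_GxE = 1,
                                            sigma2_res = 1, seed = 7))
  vc <- variance_components(big, "trait_01")
  expect_lt(abs(vc$sigma2_G - 2) / 2, 0.25)
  expect_lt(abs(vc$sigma2_GxE - 1), 0.25)
  expect_lt(abs(vc$sigma2_res - 1), 0.25)

  # permuting genotype labels destroys the genetic variance
  perm <- big
  set.seed(1); perm$genotype <- sample(perm$genotype)
  vcp <- variance_components(perm, "trait_01")
  expect_lt(vcp$sigma2_G, 0.2)
})

test_that("the simulated table reports the heritability implied by its variances", {
  tab <- simulate_phenotypes(pheno_sim_spec(n_genotypes = 10, replicates = 3,
                                            sigma2_G = 2, sigma2_GxE = 1,
                                            sigma2_res = 1, seed = 1))
  # sigma_G / (sigma_G + sigma_GxE / e + sigma_res / re), e = 2, re = 6
  expect_equal(attr(tab, "true_h2"), 2 / (2 + 1 / 2 + 1 / 6))
  expect_equal(attr(tab, "true_h2"), 0.75)
})
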