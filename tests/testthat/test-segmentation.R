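test_that("fixed thresholding keeps exactly the voxels above the level", {
  d <- array(0L, c(5, 5, 5)); d[3, 3, 3] <- 255L
  vol <- voxel_volume(d, volume_meta(5, 5, 5, 110, 8))
  mask <- threshold_volume(vol, "fixed", level = 128)
  expect_equal(sum(mask$mask), 1)
  expect_true(mask$mask[3, 3, 3])
  expect_equal(mask$provenance$level, 128)

  # degenerate all-background result is flagged, not silent
  expect_warning(empty <- threshold_volume(vol, "fixed", level = 255),
                 "degenerate")
  expect_equal(empty$provenance$flag, "empty_mask")
})

test_that("otsu separates a bimodal air/root volume and recovers the root", {
  set.seed(11)
  truth <- array(FALSE, c(30, 30, 30)); truth[8:22, 8:22, 8:22] <- TRUE
  inten <- array(round(rnorm(27000, 20, 5)), c(30, 30, 30))
  inten[truth] <- round(rnorm(sum(truth), 200, 10))
  inten[inten < 0] <- 0L; inten[inten > 255] <- 255L
  vol <- voxel_volume(inten, volume_meta(30, 30, 30, 110, 8))
  mask <- threshold_volume(vol, "otsu")
  expect_gt(mask$provenance$level, 25)   # above the air mode
  expect_lt(mask$provenance$level, 180)  # below the root mode
  recovered <- sum(mask$mask & truth) / sum(truth)
  expect_gte(recovered, 0.99)
})

test_that("thresholding is monotone and idempotent on binary data", {
  set.seed(3)
  d <- array(sample.int(256L, 1000, replace = TRUE) - 1L, c(10, 10, 10))
  vol <- voxel_volume(d, volume_meta(10, 10, 10, 110, 8))
  sizes <- vapply(c(10, 60, 120, 200), function(l)
    sum(threshold_volume(vol, "fixed", level = l)$mask), 0)
  expect_true(all(diff(sizes) <= 0))

  m1 <- threshold_volume(vol, "fixed", level = 128)
  vol01 <- voxel_volume(array(as.integer(m1$mask), dim(m1$mask)),
                        volume_meta(10, 10, 10, 110, 8))
  expect_identical(threshold_volume(vol01, "fixed", level = 0)$mask, m1$mask)
})

test_that("clean_mask removes specks, keeps the blob, and is idempotent", {
  m <- array(FALSE, c(40, 40, 40))
  m[5:14, 5:14, 5:14] <- TRUE                      # 1000-voxel blob
  speck_at <- cbind(seq(20, 38, 2), 30, 30)        # ten 2-voxel specks
  for (i in seq_len(nrow(speck_at))) {
    m[speck_at[i, 1], 30, 30] <- TRUE
    m[speck_at[i, 1], 31, 30] <- TRUE
  }
  bv <- binary_volume(m, volume_meta(40, 40, 40, 110))
  cleaned <- clean_mask(bv, min_component_voxels = 10)
  expect_equal(sum(cleaned$mask), 1000)
  expect_identical(clean_mask(cleaned, 10)$mask, cleaned$mask)  # idempotent
  expect_identical(clean_mask(bv, 1)$mask, bv$mask)             # min=1 identity
})

test_that("keep=largest breaks exact ties by lowest (z, y, x) seed", {
  m <- array(FALSE, c(20, 20, 20))
  m[2:4, 2:4, 2:4] <- TRUE      # 27 voxels, seed z=2
  m[10:12, 10:12, 10:12] <- TRUE # 27 voxels, seed z=10
  bv <- binary_volume(m, volume_meta(20, 20, 20, 110))
  kept <- clean_mask(bv, keep = "largest")
  expect_equal(sum(kept$mask), 27)
  expect_true(kept$mask[2, 2, 2])
  expect_false(kept$mask[10, 10, 10])
})

test_that("downsampling pools blocks and rescales the voxel size", {
  cyl <- fix_cylinder(r = 6, h = 40)
  ds <- downsample_mask(cyl, 2)
  expect_equal(ds$meta$voxel_size_um, 200)
  v1 <- sum(cyl$mask) * (100e-4)^3
  v2 <- sum(ds$mask) * (200e-4)^3
  expect_rel_error(v2, v1, 0.15)
})
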