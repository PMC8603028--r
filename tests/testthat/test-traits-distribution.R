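test_that("vertical profiles of a uniform cylinder are flat with solidity ~1", {
  cyl <- fix_cylinder(r = 8, h = 32)
  vp <- vertical_profile(cyl, n_slabs = 4)
  expect_true(is.na(vp$flag))
  expect_lte(diff(range(vp$biomass)), 1e-9)    # 8 slices per slab exactly
  expect_equal(sum(vp$biomass), sum(cyl$mask)) # biomass partitions the mask
  # a digital disc of radius 8 has solidity ~0.87 against its corner hull
  expect_true(all(vp$solidity > 0.8))
  expect_true(all(vp$solidity <= 1))
})

test_that("a cone profile has strictly decreasing biomass with depth", {
  n <- 61
  m <- array(FALSE, c(n, n, 60))
  for (z in 1:60) {
    r <- 28 * (1 - z / 62)
    m[, , z] <- outer((1:n - 31)^2, (1:n - 31)^2, "+") <= r^2
  }
  bv <- binary_volume(m, volume_meta(n, n, 60, 100))
  vp <- vertical_profile(bv, n_slabs = 6)
  expect_true(all(diff(vp$biomass) < 0))
})

test_that("slab solidity drops when the slab holds disjoint tubes", {
  m <- array(FALSE, c(40, 40, 30))
  c1 <- outer((1:40 - 10)^2, (1:40 - 20)^2, "+") <= 16
  c2 <- outer((1:40 - 30)^2, (1:40 - 20)^2, "+") <= 16
  for (z in 1:30) m[, , z] <- c1 | c2
  vp <- vertical_profile(binary_volume(m, volume_meta(40, 40, 30, 100)), 3)
  expect_true(all(vp$solidity < 0.75))
})

test_that("a crown shallower than n_slabs is flagged missing", {
  disc <- array(FALSE, c(20, 20, 6)); disc[5:15, 5:15, 3] <- TRUE
  vp <- vertical_profile(binary_volume(disc, volume_meta(20, 20, 6, 100)), 20)
  expect_equal(vp$flag, "shallower_than_n_slabs")
  expect_true(all(is.na(vp$biomass)))
})

test_that("distribution statistics match hand-computed references", {
  u <- distribution_stats(rep(3, 20))
  expect_equal(u$energy, 0.05)
  expect_equal(u$entropy, log2(20))
  expect_equal(u$skewness, 0)
  expect_equal(u$smoothness, 0)

  d <- distribution_stats(c(0.5, 0.25, 0.25))
  expect_equal(d$energy, 0.375)
  expect_equal(d$entropy, 1.5)

  point <- distribution_stats(c(0, 0, 9, 0, 0))
  expect_equal(point$energy, 1)
  expect_equal(point$entropy, 0)

  expect_true(all(is.na(unlist(distribution_stats(c(0, 0, 0))))))
})

test_that("distribution statistics are invariant to uniform rescaling", {
  set.seed(8)
  v <- rexp(20)
  a <- distribution_stats(v)
  b <- distribution_stats(v * 37.5)
  expect_equal(a, b)
})

test_that("energy and entropy move oppositely under concentration", {
  flat <- rep(1, 16)
  for (alpha in c(0.25, 0.5, 1, 2)) {
    peaked <- exp(-alpha * abs(seq_len(16) - 8))
    a <- distribution_stats(flat); b <- distribution_stats(peaked)
    expect_gt(b$energy, a$energy)
    expect_lt(b$entropy, a$entropy)
  }
})

test_that("radial density profiles distinguish solid, centred and annular crowns", {
  cyl <- fix_cylinder(r = 15, h = 30)
  ds <- density_s(cyl)
  expect_true(all(ds >= 0 & ds <= 1))
  expect_lt(diff(range(ds)), 0.15)          # radially uniform

  n <- 41
  ann <- outer((1:n - 21)^2, (1:n - 21)^2, "+") <= 15^2 &
         outer((1:n - 21)^2, (1:n - 21)^2, "+") >= 10^2
  m <- array(FALSE, c(n, n, 30)); for (z in 1:30) m[, , z] <- ann
  dsa <- density_s(binary_volume(m, volume_meta(n, n, 30, 100)))
  expect_true(all(diff(dsa) >= 0))          # mass pushed outward

  core <- fix_cylinder(r = 4, h = 30)
  # pad so the core fills only the innermost shells of its own extent
  dsc <- density_s(core)
  expect_gt(dsc[1], 0.9)
})
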