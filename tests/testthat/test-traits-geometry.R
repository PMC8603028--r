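test_that("cube volume is exact and surface area is within 5% of 6 s^2", {
  cube <- fix_cube(10, voxel_um = 100)
  vs <- volume_and_surface(cube)
  expect_equal(vs$Volume, 0.001)                     # 1000 voxels x 1e-6 cm^3
  expect_rel_error(vs$SurfaceArea, 0.06, 0.05)
  ch <- convex_hull_traits(cube)
  expect_gt(ch$Solidity, 0.97)
  expect_lte(ch$Solidity, 1)
})

test_that("sphere volume and surface area match the analytic ball", {
  sph <- fix_sphere(20, voxel_um = 100)
  vs <- volume_and_surface(sph)
  s <- 100e-4
  expect_rel_error(vs$Volume, (4 / 3) * pi * 20^3 * s^3, 0.02)
  expect_rel_error(vs$SurfaceArea, 4 * pi * 20^2 * s^2, 0.05)
  ex <- extent_traits(sph)
  expect_lt(abs(ex$Elongation - 1), 0.1)
})

test_that("convex hull volume matches exact polytopes and ignores interior voxels", {
  # hull over voxel cell corners: a full cube of side s has hull volume s^3
  cube <- fix_cube(8)
  full <- convex_hull_traits(cube)$ConvexHullVolume
  expect_rel_error(full, 8^3 * (100e-4)^3, 1e-6)
  # carving out the interior leaves the hull unchanged
  m <- cube$mask; m[3:6, 3:6, 3:6] <- FALSE
  hollow <- convex_hull_traits(binary_volume(m, cube$meta))$ConvexHullVolume
  expect_equal(hollow, full)
  # exact tetrahedron oracle: 4 cell-corner points
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(0, 0, 5))
  expect_equal(rootcrown:::.hull3d_volume(pts), 3 * 4 * 5 / 6)
  # octahedron: |x|+|y|+|z| <= c has volume 4 c^3 / 3
  oc <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
              c(0, 0, 3), c(0, 0, -3))
  expect_equal(rootcrown:::.hull3d_volume(oc), 4 * 27 / 3)
  # a single occupied slab still has a 3D cell hull (corner convention)
  flat <- array(FALSE, c(5, 5, 5)); flat[, , 3] <- TRUE
  res <- convex_hull_traits(binary_volume(flat, volume_meta(5, 5, 5, 100)))
  expect_rel_error(res$ConvexHullVolume, 25 * (100e-4)^3, 1e-6)
  expect_equal(res$Solidity, 1)
})

test_that("two corner blobs give a low-solidity spanning hull", {
  m <- array(FALSE, c(20, 20, 20))
  m[1:4, 1:4, 1:4] <- TRUE
  m[17:20, 17:20, 17:20] <- TRUE
  bv <- binary_volume(m, volume_meta(20, 20, 20, 100))
  ch <- convex_hull_traits(bv)
  expect_lt(ch$Solidity, 0.2)
  # the hull spans a region far larger than the two blobs
  expect_gt(ch$ConvexHullVolume, 5 * sum(m) * (100e-4)^3)
})

test_that("extent traits recover depth, width and elongation of a cylinder", {
  cyl <- fix_cylinder(r = 5, h = 100, voxel_um = 100)
  ex <- extent_traits(cyl)
  expect_equal(ex$Depth, 100 * 100e-4)
  expect_rel_error(ex$HorEqDiameter, 10 * 100e-4, 0.12)
  expect_rel_error(ex$Elongation, 10, 0.12)
  expect_equal(ex$WidthDepthRatio, ex$HorEqDiameter / ex$Depth)

  disc <- array(FALSE, c(20, 20, 5))
  disc[, , 3] <- outer((1:20 - 10)^2, (1:20 - 10)^2, "+") <= 36
  ex2 <- extent_traits(binary_volume(disc, volume_meta(20, 20, 5, 100)))
  expect_equal(ex2$Depth, 100e-4)       # single-slice disc: depth = 1 voxel
})

test_that("slice root counts see branches and match a flood-fill census", {
  cyl <- fix_cylinder()
  rc <- slice_root_counts(cyl)
  expect_equal(rc$MaxRootCount, 1)
  expect_equal(rc$MedianRootCount, 1)

  # trunk splitting into 4 separated branches halfway down
  m <- array(FALSE, c(40, 40, 60))
  circ <- function(cx, cy, r) outer((1:40 - cx)^2, (1:40 - cy)^2, "+") <= r^2
  for (z in 1:30) m[, , z] <- circ(20, 20, 6)
  for (z in 31:60)
    m[, , z] <- circ(10, 10, 3) | circ(30, 10, 3) | circ(10, 30, 3) |
                circ(30, 30, 3)
  bv <- binary_volume(m, volume_meta(40, 40, 60, 100))
  rc2 <- slice_root_counts(bv)
  expect_equal(rc2$MaxRootCount, 4)
  expect_equal(rc2$MedianRootCount, 2.5)
  expect_equal(rc2$Bushiness, 4 / 2.5)
})

test_that("fractal dimension hits the plane, line and Sierpinski limits", {
  sq <- array(FALSE, c(64, 2, 64)); sq[, 1, ] <- TRUE
  fd_sq <- fractal_dimension(binary_volume(sq, volume_meta(64, 2, 64, 100)),
                             "side")
  expect_lt(abs(fd_sq - 2), 0.1)

  ln <- array(FALSE, c(64, 2, 64)); ln[, 1, 32] <- TRUE
  fd_ln <- fractal_dimension(binary_volume(ln, volume_meta(64, 2, 64, 100)),
                             "side")
  expect_lt(abs(fd_ln - 1), 0.1)

  fd_cp <- fractal_dimension(fix_carpet(5), "side")
  expect_lt(abs(fd_cp - log(8) / log(3)), 0.05)

  tiny <- array(FALSE, c(3, 3, 3)); tiny[2, 2, 2] <- TRUE
  expect_true(is.na(fractal_dimension(
    binary_volume(tiny, volume_meta(3, 3, 3, 100)), "top")))
})

test_that("traits obey scale equivariance in the voxel size", {
  sph <- fix_sphere(12, voxel_um = 100)
  sph2 <- binary_volume(sph$mask, volume_meta(dim(sph$mask)[1],
                        dim(sph$mask)[2], dim(sph$mask)[3], 200))
  a <- volume_and_surface(sph); b <- volume_and_surface(sph2)
  expect_equal(b$Volume, a$Volume * 8)
  expect_equal(b$SurfaceArea, a$SurfaceArea * 4)
  expect_equal(extent_traits(sph2)$Depth, extent_traits(sph)$Depth * 2)
  expect_equal(convex_hull_traits(sph2)$Solidity,
               convex_hull_traits(sph)$Solidity)
  expect_equal(fractal_dimension(sph2, "top"), fractal_dimension(sph, "top"))
})
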