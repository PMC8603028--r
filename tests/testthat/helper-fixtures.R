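# Analytic voxel fixtures shared across the suite. All are built in code;
# geometry is exact so tests can compare against closed forms.

fix_meta <- function(d, voxel_um = 100) volume_meta(d[1], d[2], d[3], voxel_um)

fix_cube <- function(side = 10, voxel_um = 100) {
  binary_volume(array(TRUE, c(side, side, side)),
                fix_meta(c(side, side, side), voxel_um))
}

fix_sphere <- function(r = 20, voxel_um = 100) {
  n <- 2 * r + 11
  ix <- seq_len(n); c0 <- (n + 1) / 2
  m <- outer(outer((ix - c0)^2, (ix - c0)^2, "+"), (ix - c0)^2, "+") <= r^2
  binary_volume(m, fix_meta(c(n, n, n), voxel_um))
}

# solid cylinder along z, radius r, height h
fix_cylinder <- function(r = 5, h = 100, voxel_um = 100) {
  n <- 2 * r + 11
  ix <- seq_len(n); c0 <- (n + 1) / 2
  circ <- outer((ix - c0)^2, (ix - c0)^2, "+") <= r^2
  m <- array(FALSE, c(n, n, h + 4))
  for (z in seq_len(h)) m[, , z + 2] <- circ
  binary_volume(m, fix_meta(c(n, n, h + 4), voxel_um))
}

# Y-shaped tube: vertical trunk splitting into two oblique branches
fix_y <- function(r = 3, voxel_um = 100) {
  seg <- function(p0, p1, n = 200)
    cbind(seq(p0[1], p1[1], length.out = n),
          seq(p0[2], p1[2], length.out = n),
          seq(p0[3], p1[3], length.out = n))
  pts <- rbind(seg(c(30, 30, 5), c(30, 30, 40)),
               seg(c(30, 30, 40), c(15, 30, 70)),
               seg(c(30, 30, 40), c(45, 30, 70)))
  dims <- c(60L, 60L, 75L)
  m <- array(rootcrown:::.stamp_spheres(pts, rep(r, nrow(pts)), dims,
                                        array(FALSE, dims)), dims)
  binary_volume(m, fix_meta(dims, voxel_um))
}

# Sierpinski carpet of side 3^k as a one-slab volume (side projection)
fix_carpet <- function(k = 5, voxel_um = 100) {
  carpet <- function(n) {
    if (n == 1) return(matrix(TRUE, 1, 1))
    s <- carpet(n / 3)
    z <- matrix(FALSE, nrow(s), ncol(s))
    rbind(cbind(s, s, s), cbind(s, z, s), cbind(s, s, s))
  }
  cp <- carpet(3^k)
  m <- array(FALSE, c(3^k, 1, 3^k)); m[, 1, ] <- cp
  binary_volume(m, fix_meta(c(3^k, 1L, 3^k), voxel_um))
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value / truth - 1), tol)
}
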