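# Calibrated local-configuration surface area estimation.
#
# Every 2x2x2 cell of the (zero-padded) mask is an 8-bit configuration,
# folded to a canonical class under the 48 cube symmetries and inside/outside
# complementation (the isosurface is the same either way). Each class carries
# a fixed area contribution in voxel^2; flat axis-aligned interfaces are the
# "quad" class with weight exactly 1, so planar faces are measured exactly.
# The 2-adjacent-corner class is ambiguous — it appears both on sharp
# 90-degree edges (1D chains of such cells) and on 45-degree walls (2D
# sheets) with different true areas — and is split by whether a face
# neighbour perpendicular to the corner-pair axis carries the same class.
# The remaining weights were calibrated by nonnegative least squares on
# digitized balls, cubes, boxes, cylinders and ellipsoids with analytic
# areas; scripts/calibrate-surface-weights.R regenerates them.

# 8-bit cell configurations: bit = x + 2y + 4z of the corner within the cell.
surface_symmetry_tables <- function() {
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  perms <- list()
  for (p in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)))
    for (sx in c(1,-1)) for (sy in c(1,-1)) for (sz in c(1,-1))
      perms[[length(perms) + 1L]] <- list(p = p, s = c(sx, sy, sz))
  maps <- lapply(perms, function(pr) {
    newc <- sweep((corners - 0.5)[, pr$p, drop = FALSE], 2L, pr$s, "*") + 0.5
    apply(round(newc), 1L, function(cc)
      which(corners[, 1] == cc[1] & corners[, 2] == cc[2] & corners[, 3] == cc[3]))
  })
  bits <- function(cfg) as.integer(bitwAnd(bitwShiftR(cfg, 0:7), 1L))
  canon <- integer(256)
  pax <- integer(256); pax[] <- -1L
  for (cfg in 0:255) {
    b <- bits(cfg)
    vals <- vapply(maps, function(m) sum(b[m] * 2^(0:7)), 0)
    canon[cfg + 1L] <- as.integer(min(c(vals, 255 - vals)))
    ins <- which(b == 1L)
    mino <- if (length(ins) == 2L) ins else if (length(ins) == 6L) which(b == 0L) else integer(0)
    if (length(mino) == 2L) {
      d <- abs(corners[mino[1L], ] - corners[mino[2L], ])
      if (sum(d) == 1L) pax[cfg + 1L] <- which(d == 1L) - 1L  # 0=x,1=y,2=z
    }
  }
  list(canon = canon, pax = pax,
       quad_class = canon[15 + 1L],   # 4 corners of the z = 0 face
       edge_class = canon[3 + 1L])    # 2 axis-adjacent corners
}

.surface_env <- new.env(parent = emptyenv())

surface_tables <- function() {
  if (is.null(.surface_env$tab))
    .surface_env$tab <- surface_symmetry_tables()
  .surface_env$tab
}

# Count cells per feature: named vector with canonical class ids plus
# "edge3"/"sheet3" context splits of the edge class.
surface_feature_counts <- function(mask3d) {
  tab <- surface_tables()
  cnt <- .surface_cells(mask3d, dim(mask3d), tab$canon, tab$pax, tab$edge_class)
  classes <- sort(setdiff(unique(tab$canon), 0L))
  out <- cnt[classes + 1L]
  names(out) <- as.character(classes)
  out[as.character(tab$edge_class)] <- 0L  # replaced by the split below
  c(out, edge3 = cnt[257L], sheet3 = cnt[258L])
}

# Estimated surface area of the mask in voxel^2 units.
surface_area_vx2 <- function(mask3d) {
  w <- surface_calibration_weights()
  feats <- surface_feature_counts(mask3d)
  sum(feats * w[names(feats)])
}
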