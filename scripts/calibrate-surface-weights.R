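#!/usr/bin/env Rscript
# Regenerates R/surface-weights.R: area weights for the local 2x2x2
# configuration surface estimator, fit by nonnegative least squares on a
# library of digitized solids with analytic surface areas (balls, cubes,
# boxes, cylinders, ellipsoids — the curvature range of root organs).
# The flat axis-aligned interface (quad class) is fixed at exactly 1.
# Usage: Rscript scripts/calibrate-surface-weights.R   (from the repo root,
# with the package installed). Requires pracma for lsqnonneg.

library(rootcrown)

counts_of <- function(mask3d) rootcrown:::surface_feature_counts(mask3d)

ball <- function(r) {
  n <- 2 * r + 9; ix <- seq_len(n); c0 <- (n + 1) / 2
  outer(outer((ix - c0)^2, (ix - c0)^2, "+"), (ix - c0)^2, "+") <= r^2
}
cylinder <- function(r, h) {
  n <- 2 * r + 9; ix <- seq_len(n); c0 <- (n + 1) / 2
  circ <- outer((ix - c0)^2, (ix - c0)^2, "+") <= r^2
  m <- array(FALSE, c(n, n, h + 8))
  for (z in seq_len(h)) m[, , z + 4] <- circ
  m
}
ellipsoid <- function(a, b, c3) {
  n <- 2 * max(a, b, c3) + 9; ix <- seq_len(n); c0 <- (n + 1) / 2
  arr <- array(FALSE, c(n, n, n))
  for (z in seq_len(n))
    arr[, , z] <- outer((ix - c0)^2 / a^2, (ix - c0)^2 / b^2, "+") +
      (z - c0)^2 / c3^2 <= 1
  arr
}
ell_area <- function(a, b, c3) {        # Thomsen approximation
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c3^p + b^p * c3^p) / 3)^(1 / p)
}

rows <- list(); areas <- c()
add <- function(mask, area) {
  rows[[length(rows) + 1L]] <<- counts_of(mask)
  areas <<- c(areas, area)
}
for (r in c(4, 6, 8, 10, 12, 16, 20, 25)) add(ball(r), 4 * pi * r^2)
for (s in c(6, 8, 10, 14, 20, 26, 30)) add(array(TRUE, c(s, s, s)), 6 * s^2)
for (d in list(c(6, 10, 20), c(8, 16, 24), c(5, 25, 25), c(12, 12, 30)))
  add(array(TRUE, d), 2 * (d[1] * d[2] + d[2] * d[3] + d[1] * d[3]))
for (rh in list(c(2, 30), c(3, 30), c(4, 40), c(5, 40), c(6, 40),
                c(8, 40), c(10, 50), c(12, 50)))
  add(cylinder(rh[1], rh[2]), 2 * pi * rh[1] * rh[2] + 2 * pi * rh[1]^2)
for (abc in list(c(8, 12, 20), c(6, 18, 18), c(10, 10, 25)))
  add(ellipsoid(abc[1], abc[2], abc[3]), ell_area(abc[1], abc[2], abc[3]))

X <- do.call(rbind, rows)
feat <- colnames(X)
tab <- rootcrown:::surface_tables()
quad <- as.character(tab$quad_class)

# relative-error least squares with the quad weight pinned at 1
Xs <- X / areas
rhs <- 1 - Xs[, quad]
keep <- setdiff(feat, quad)
fit <- pracma::lsqnonneg(Xs[, keep], rhs)
w <- stats::setNames(numeric(length(feat)), feat)
w[keep] <- fit$x
w[quad] <- 1

pred <- as.numeric(X %*% w)
cat(sprintf("calibration: mean |rel err| %.2f%%, max %.2f%% over %d solids\n",
            100 * mean(abs(pred / areas - 1)),
            100 * max(abs(pred / areas - 1)), length(areas)))

lines <- c(
  "# Generated by scripts/calibrate-surface-weights.R — do not edit by hand.",
  "# Area contribution (voxel^2) per canonical 2x2x2 boundary-cell class;",
  "# \"edge3\"/\"sheet3\" are the context split of the 2-adjacent-corner class",
  "# (sharp 90-degree edge chains vs 45-degree sheets). The quad class (flat",
  "# axis-aligned interface) is fixed at exactly 1; the rest were fit by",
  "# nonnegative least squares on digitized balls, cubes, boxes, cylinders",
  "# and ellipsoids with analytic surface areas.",
  "surface_calibration_weights <- function() {",
  paste0("  c(", paste(sprintf("`%s` = %.6g", names(w), w), collapse = ", "),
         ")"),
  "}")
writeLines(lines, "R/surface-weights.R")
cat("wrote R/surface-weights.R\n")
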