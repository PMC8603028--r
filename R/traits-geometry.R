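um_per_cm <- 1e4

vox_cm <- function(meta) meta$voxel_size_um / um_per_cm

#' Whole-crown volume and surface area
#'
#' Volume is the voxel count times the voxel volume. Surface area is
#' estimated from local 2x2x2 boundary configurations with calibrated area
#' weights (flat axis-aligned interfaces are exact; curved surfaces agree
#' with analytic spheres and cylinders to within a few percent — see the
#' methods vignette for the calibration).
#'
#' @param mask A nonempty [binary_volume()].
#' @return List with `Volume` (cm^3) and `SurfaceArea` (cm^2).
#' @export
volume_and_surface <- function(mask) {
  if (!any(mask$mask)) stop("empty mask")
  s <- vox_cm(mask$meta)
  list(Volume = sum(mask$mask) * s^3,
       SurfaceArea = surface_area_vx2(mask$mask) * s^2)
}

# Candidate voxels for the 3D hull: on each axis-aligned line, only the
# first and last root voxel can be a hull vertex (any supporting direction
# has a nonzero component along some axis).
hull_candidate_voxels <- function(m) {
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  keep <- rep(FALSE, nrow(idx))
  for (axes in list(c(2L, 3L), c(1L, 3L), c(1L, 2L))) {
    line <- idx[, axes[1L]] + (d[axes[1L]] + 1L) * idx[, axes[2L]]
    other <- setdiff(1:3, axes)
    ord <- order(line, idx[, other])
    li <- line[ord]
    first <- !duplicated(li)
    last <- !duplicated(li, fromLast = TRUE)
    keep[ord[first | last]] <- TRUE
  }
  idx[keep, , drop = FALSE]
}

#' Convex hull volume and solidity
#'
#' The hull is taken over the corners of the root voxel cells (centres
#' +/- half a voxel), so that the mask volume can never exceed the hull
#' volume and Solidity = Volume / ConvexHullVolume lies in (0, 1].
#'
#' @param mask A [binary_volume()] with at least 4 non-coplanar voxels.
#' @return List with `ConvexHullVolume` (cm^3) and `Solidity`; both `NA`
#'   (flagged degenerate) when the voxels are coplanar.
#' @export
convex_hull_traits <- function(mask) {
  if (!any(mask$mask)) stop("empty mask")
  cand <- hull_candidate_voxels(mask$mask)
  corners <- expand.grid(dx = c(-0.5, 0.5), dy = c(-0.5, 0.5),
                         dz = c(-0.5, 0.5))
  pts <- do.call(rbind, lapply(seq_len(nrow(corners)), function(k)
    sweep(cand - 0.5, 2L, as.numeric(corners[k, ]), "+")))
  pts <- unique(pts)
  hull_vx3 <- .hull3d_volume(as.matrix(pts))
  if (hull_vx3 <= 0)
    return(list(ConvexHullVolume = NA_real_, Solidity = NA_real_))
  s <- vox_cm(mask$meta)
  vol <- sum(mask$mask) * s^3
  hull <- hull_vx3 * s^3
  list(ConvexHullVolume = hull, Solidity = min(vol / hull, 1))
}

# Shoelace area of the 2D hull over pixel corners; pts = n x 2 pixel centres.
hull2d_area <- function(pts) {
  if (nrow(pts) == 0L) return(0)
  corners <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(-0.5, 0.5), c(0.5, 0.5))
  p <- unique(do.call(rbind, lapply(1:4, function(k)
    sweep(pts, 2L, corners[k, ], "+"))))
  if (nrow(p) < 3L) return(0)
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(0)
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Depth, horizontal equivalent diameter, elongation
#'
#' Depth spans the occupied z range. The crown width `HorEqDiameter` is the
#' diameter of the circle whose area equals the maximal horizontal-slice
#' convex area; Elongation = Depth / HorEqDiameter.
#'
#' @param mask A nonempty [binary_volume()].
#' @return List with `Depth` (cm), `HorEqDiameter` (cm), `Elongation`,
#'   `WidthDepthRatio`.
#' @export
extent_traits <- function(mask) {
  if (!any(mask$mask)) stop("empty mask")
  s <- vox_cm(mask$meta)
  zocc <- which(apply(mask$mask, 3L, any))
  depth <- (max(zocc) - min(zocc) + 1L) * s
  max_area_vx2 <- 0
  for (z in zocc) {
    pts <- which(mask$mask[, , z], arr.ind = TRUE)
    a <- hull2d_area(pts)
    if (a > max_area_vx2) max_area_vx2 <- a
  }
  hed <- 2 * sqrt(max_area_vx2 / pi) * s
  list(Depth = depth, HorEqDiameter = hed,
       Elongation = depth / hed, WidthDepthRatio = hed / depth)
}

#' Per-slice root counts
#'
#' Roots crossing a horizontal plane appear as distinct 8-connected 2D
#' components; the maximum and the median over nonempty slices summarize
#' how many roots the crown carries.
#'
#' @param mask A nonempty [binary_volume()].
#' @return List with `MaxRootCount`, `MedianRootCount` and `Bushiness`
#'   (max / median).
#' @export
slice_root_counts <- function(mask) {
  if (!any(mask$mask)) stop("empty mask")
  d <- dim(mask$mask)
  counts <- vapply(seq_len(d[3]), function(z) {
    sl <- mask$mask[, , z]
    if (!any(sl)) return(NA_integer_)
    lab <- .cc_label(sl, c(d[1], d[2], 1L), 26L)  # 26-conn on 1 slice = 8-conn
    attr(lab, "n")
  }, 1L)
  counts <- counts[!is.na(counts)]
  med <- stats::median(counts)
  list(MaxRootCount = max(counts), MedianRootCount = med,
       Bushiness = max(counts) / med)
}

#' Box-counting fractal dimension of a 2D projection
#'
#' The mask is projected to a binary image (side view: along y; top view:
#' along z), cropped to its bounding box, and covered with boxes of size
#' 1, 2, 4, ..., 2^k voxels (k = floor(log2(min(dim)))), anchored at the
#' bounding-box corner. The dimension is the least-squares slope of
#' log N(s) against log(1/s). Plane-filling projections approach 2, thin
#' lines approach 1.
#'
#' @param mask A nonempty [binary_volume()].
#' @param view `"side"` or `"top"`.
#' @param offset_average Average counts over all grid anchor offsets at each
#'   box size instead of the single corner anchor (slower; default `FALSE`).
#' @return Dimension in `[0, 2]`, or `NA` when the projection is smaller
#'   than 4 x 4.
#' @export
fractal_dimension <- function(mask, view = c("side", "top"),
                              offset_average = FALSE) {
  view <- match.arg(view)
  proj <- if (view == "side") apply(mask$mask, c(1, 3), any)
          else apply(mask$mask, c(1, 2), any)
  box_counting_dimension(proj, offset_average)
}

box_counting_dimension <- function(proj, offset_average = FALSE) {
  occ <- which(proj, arr.ind = TRUE)
  if (!nrow(occ)) return(NA_real_)
  d <- dim(proj)
  if (min(d) < 4L) return(NA_real_)
  # anchor the grid at the bounding-box corner; box sizes span the image
  proj <- proj[min(occ[, 1]):max(occ[, 1]), min(occ[, 2]):max(occ[, 2]),
               drop = FALSE]
  k <- floor(log2(min(d)))
  sizes <- 2^(0:k)
  counts <- vapply(sizes, function(s) {
    if (!offset_average) return(count_boxes(proj, s, 0L, 0L))
    offs <- expand.grid(ox = 0:(s - 1L), oy = 0:(s - 1L))
    mean(vapply(seq_len(nrow(offs)), function(i)
      count_boxes(proj, s, offs$ox[i], offs$oy[i]), 0))
  }, 0)
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  unname(stats::coef(fit)[2L])
}

count_boxes <- function(proj, s, ox, oy) {
  if (s == 1L) return(sum(proj))
  idx <- which(proj, arr.ind = TRUE)
  bx <- (idx[, 1] - 1L + ox) %/% s
  by <- (idx[, 2] - 1L + oy) %/% s
  length(unique(bx + (max(bx) + 1L) * by))
}
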