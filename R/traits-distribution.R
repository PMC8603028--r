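#' Vertical profile of the root crown
#'
#' The occupied depth range is partitioned into `n_slabs` equal-depth bins
#' (slab 1 at the top, the stem end). Each slab records its biomass (root
#' voxel count), the 2D convex-hull area of its horizontal projection
#' (cm^2, hull over pixel corners) and its solidity (projected root area /
#' hull area, in [0, 1], `NA` when the hull is degenerate).
#'
#' @param mask A nonempty [binary_volume()].
#' @param n_slabs Number of vertical bins; default 20. The crown must be at
#'   least `n_slabs` voxels deep, otherwise the profile is flagged missing.
#' @return A `vertical_profile`: list with `n_slabs`, `biomass`,
#'   `hull_area_cm2`, `solidity` (each length `n_slabs`) and `flag`.
#' @export
vertical_profile <- function(mask, n_slabs = 20L) {
  if (n_slabs < 2L) stop("n_slabs must be >= 2")
  if (!any(mask$mask)) stop("empty mask")
  zocc <- which(apply(mask$mask, 3L, any))
  z0 <- min(zocc); z1 <- max(zocc)
  depth <- z1 - z0 + 1L
  if (depth < n_slabs)
    return(structure(list(n_slabs = n_slabs, biomass = rep(NA_real_, n_slabs),
                          hull_area_cm2 = rep(NA_real_, n_slabs),
                          solidity = rep(NA_real_, n_slabs),
                          flag = "shallower_than_n_slabs"),
                     class = "vertical_profile"))
  s <- vox_cm(mask$meta)
  # slab k covers z in [z0 + (k-1) d/n, z0 + k d/n)
  breaks <- z0 + depth * (0:n_slabs) / n_slabs
  slab_of <- findInterval(seq(z0, z1) + 0.5, breaks, rightmost.closed = TRUE)
  biomass <- numeric(n_slabs)
  hull_area <- numeric(n_slabs)
  solidity <- rep(NA_real_, n_slabs)
  for (k in seq_len(n_slabs)) {
    zs <- seq(z0, z1)[slab_of == k]
    if (!length(zs)) next
    slab <- mask$mask[, , zs, drop = FALSE]
    biomass[k] <- sum(slab)
    proj <- apply(slab, c(1, 2), any)
    pts <- which(proj, arr.ind = TRUE)
    a_vx2 <- hull2d_area(pts)
    hull_area[k] <- a_vx2 * s^2
    if (a_vx2 > 0) solidity[k] <- min(sum(proj) / a_vx2, 1)
  }
  structure(list(n_slabs = n_slabs, biomass = biomass,
                 hull_area_cm2 = hull_area, solidity = solidity,
                 flag = NA_character_),
            class = "vertical_profile")
}

#' Summary statistics of a nonnegative profile
#'
#' The profile is normalized to a discrete distribution over slab indices,
#' `p_k = v_k / sum(v)`, and summarized by seven texture-style descriptors:
#' mean and standard deviation of the slab index under `p`; skewness and
#' kurtosis as the third and fourth standardized moments; energy
#' `sum(p^2)` (1 when all mass is in one slab, `1/n` when uniform); entropy
#' `-sum(p log2 p)` in bits (0 log 0 := 0); and smoothness
#' `1 - 1/(1 + var(p))` with the variance taken over the normalized values
#' (0 for a uniform profile). Invariant to uniform rescaling of the input.
#'
#' @param values Nonnegative numeric vector, length >= 2, positive sum.
#' @return Named list: `mean`, `std`, `skewness`, `kurtosis`, `energy`,
#'   `entropy`, `smoothness`; all `NA` for an all-zero or flagged profile.
#' @export
distribution_stats <- function(values) {
  nas <- list(mean = NA_real_, std = NA_real_, skewness = NA_real_,
              kurtosis = NA_real_, energy = NA_real_, entropy = NA_real_,
              smoothness = NA_real_)
  if (length(values) < 2L || anyNA(values)) return(nas)
  if (any(values < 0)) stop("profile values must be nonnegative")
  tot <- sum(values)
  if (tot <= 0) return(nas)
  p <- values / tot
  k <- seq_along(p)
  mu <- sum(k * p)
  sdev <- sqrt(sum((k - mu)^2 * p))
  skew <- if (sdev > 0) sum(((k - mu) / sdev)^3 * p) else 0
  kurt <- if (sdev > 0) sum(((k - mu) / sdev)^4 * p) else 0
  pos <- p[p > 0]
  vp <- mean((p - mean(p))^2)
  list(mean = mu, std = sdev, skewness = skew, kurtosis = kurt,
       energy = sum(p^2), entropy = -sum(pos * log2(pos)),
       smoothness = 1 - 1 / (1 + vp))
}

#' Radial compactness profile (DensityS)
#'
#' Radial distance from the vertical axis through the horizontal centroid
#' of the crown is partitioned into `n_shells` equal-width shells up to the
#' outermost root voxel. `DensityS_k` is the fraction of the shell-k
#' bounding-cylinder voxels (over the occupied depth) that are root — a
#' radial profile of how densely the crown fills space moving outward.
#'
#' @param mask A nonempty [binary_volume()].
#' @param n_shells Number of radial shells; default 9.
#' @return Numeric vector `DensityS1..DensityS{n}` with values in [0, 1].
#' @export
density_s <- function(mask, n_shells = 9L) {
  if (!any(mask$mask)) stop("empty mask")
  d <- dim(mask$mask)
  idx <- which(mask$mask, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  zocc <- range(idx[, 3])
  r_vox <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)
  r_max <- max(r_vox)
  out <- numeric(n_shells)
  names(out) <- paste0("DensityS", seq_len(n_shells))
  if (r_max == 0) { out[1] <- 1; return(out) }
  # shell occupancy over the full xy grid restricted to the occupied depth
  gx <- rep(seq_len(d[1]), times = d[2])
  gy <- rep(seq_len(d[2]), each = d[1])
  gr <- sqrt((gx - cx)^2 + (gy - cy)^2)
  nz_occ <- zocc[2] - zocc[1] + 1L
  breaks <- r_max * (0:n_shells) / n_shells
  shell_grid <- findInterval(gr, breaks, rightmost.closed = TRUE)
  shell_grid[gr > r_max] <- 0L   # outside the outermost shell
  grid_per_shell <- tabulate(shell_grid[shell_grid >= 1L],
                             nbins = n_shells) * nz_occ
  shell_vox <- pmin(pmax(findInterval(r_vox, breaks, rightmost.closed = TRUE),
                         1L), n_shells)
  root_per_shell <- tabulate(shell_vox, nbins = n_shells)
  ok <- grid_per_shell > 0
  out[ok] <- root_per_shell[ok] / grid_per_shell[ok]
  pmin(out, 1)
}
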