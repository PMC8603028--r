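#' Threshold a grayscale volume into a root/air mask
#'
#' Washed root crowns imaged in air are high-contrast, so segmentation is a
#' global threshold: root voxels are those with intensity strictly above the
#' level. The level is either supplied (`method = "fixed"`) or chosen by
#' Otsu's criterion on the full intensity histogram (`method = "otsu"`).
#' The chosen level is recorded in the result's provenance.
#'
#' An all-background or all-foreground outcome is not an error — it is
#' returned with `provenance$flag` set and a warning, so that batch runs can
#' quarantine the sample rather than fail.
#'
#' @param vol A [voxel_volume()].
#' @param method `"fixed"` or `"otsu"`.
#' @param level Intensity threshold for `method = "fixed"`; must lie within
#'   the bit-depth range.
#' @return A [binary_volume()] with provenance `list(method, level, flag)`.
#' @export
threshold_volume <- function(vol, method = c("fixed", "otsu"), level = NULL) {
  method <- match.arg(method)
  maxval <- 2^vol$meta$bit_depth - 1
  if (method == "fixed") {
    if (is.null(level)) stop("fixed thresholding requires a level")
    if (level < 0 || level > maxval)
      stop("level outside the bit-depth range [0, ", maxval, "]")
  } else {
    level <- otsu_level(vol$data, maxval)
  }
  mask <- vol$data > level
  flag <- NA_character_
  if (!any(mask)) flag <- "empty_mask"
  if (all(mask)) flag <- "all_foreground"
  if (!is.na(flag))
    warning("thresholding produced a degenerate mask (", flag, ")")
  binary_volume(mask, vol$meta,
                provenance = list(step = "threshold", method = method,
                                  level = level, flag = flag))
}

# Otsu's between-class variance maximization on the integer histogram.
otsu_level <- function(data, maxval) {
  h <- tabulate(as.integer(data) + 1L, nbins = maxval + 1L)
  p <- h / sum(h)
  levels <- 0:maxval
  omega <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  levels[which.max(sigma_b)]
}

#' Remove small disconnected components from a mask
#'
#' CT reconstructions carry floating speckle; components (26-connectivity by
#' default) below `min_component_voxels` are removed, or only the largest
#' component is kept. Ties for the largest are broken deterministically by
#' the component whose seed voxel has the lowest (z, y, x) index. The
#' component census is recorded in the provenance. Idempotent.
#'
#' @param mask A [binary_volume()].
#' @param min_component_voxels Minimum voxels a component must have to
#'   survive (`keep = "all_above_min"`).
#' @param keep `"all_above_min"` or `"largest"`.
#' @param connectivity 26 (default) or 6.
#' @return A cleaned [binary_volume()].
#' @export
clean_mask <- function(mask, min_component_voxels = 1L,
                       keep = c("all_above_min", "largest"),
                       connectivity = 26L) {
  keep <- match.arg(keep)
  if (min_component_voxels < 1L) stop("min_component_voxels must be >= 1")
  lab <- .cc_label(mask$mask, dim(mask$mask), as.integer(connectivity))
  n <- attr(lab, "n")
  if (n == 0L) {
    warning("clean_mask on an empty mask")
    return(binary_volume(mask$mask, mask$meta,
                         provenance = list(step = "clean", flag = "empty_mask")))
  }
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep_ids <- if (keep == "largest") {
    which.max(sizes)  # first max = lowest (z,y,x) seed by construction
  } else {
    which(sizes >= min_component_voxels)
  }
  out <- array(lab %in% keep_ids & lab > 0L, dim = dim(mask$mask))
  flag <- if (!any(out)) "empty_mask" else NA_character_
  if (!is.na(flag)) warning("clean_mask removed every component")
  binary_volume(out, mask$meta,
                provenance = c(mask$provenance,
                               list(clean = list(step = "clean", keep = keep,
                                    min_component_voxels = min_component_voxels,
                                    connectivity = connectivity,
                                    n_components = n,
                                    n_removed = n - length(keep_ids),
                                    component_sizes = sizes,
                                    flag = flag))))
}

#' Integer-factor downsampling of a binary mask
#'
#' Majority (mode) pooling over non-overlapping `factor^3` blocks; the voxel
#' size is scaled so physical traits stay comparable. Off by default in the
#' pipeline; intended for speed on very large scans.
#'
#' @param mask A [binary_volume()].
#' @param factor Integer >= 2.
#' @return A [binary_volume()] with `ceiling(dim / factor)` voxels per axis.
#' @export
downsample_mask <- function(mask, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be an integer >= 2")
  d <- dim(mask$mask)
  nd <- ceiling(d / factor)
  pad <- array(FALSE, dim = nd * factor)
  pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask$mask
  # mean over blocks; majority rule at > 0.5 (strict: ties go to background)
  blk <- array(pad, dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  mean_blk <- apply(blk, c(2, 4, 6), mean)
  meta <- volume_meta(nd[1], nd[2], nd[3],
                      mask$meta$voxel_size_um * factor,
                      mask$meta$bit_depth, mask$meta$byte_order)
  binary_volume(mean_blk > 0.5, meta,
                provenance = c(mask$provenance,
                               list(downsample = list(factor = factor))))
}
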