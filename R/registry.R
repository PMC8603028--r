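.registry_env <- new.env(parent = emptyenv())

#' The registered 71-trait roster
#'
#' The single source of truth for trait names, families, units and column
#' order of every trait table the package writes. Shipped as
#' `inst/extdata/trait_registry.csv`. The roster comprises 19 classical
#' skeleton/shape traits, 2 box-counting fractal dimensions, 21 vertical
#' distribution statistics (7 descriptors x biomass / convex hull /
#' solidity profiles), 20 per-slab solidity bins and 9 radial compactness
#' shells.
#'
#' @return Data frame with columns `name`, `family`, `units`, `description`.
#' @export
trait_registry <- function() {
  if (is.null(.registry_env$reg)) {
    path <- system.file("extdata", "trait_registry.csv", package = "rootcrown")
    .registry_env$reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .registry_env$reg
}

#' Names of the registered traits, in canonical column order
#' @export
trait_names <- function() trait_registry()$name

#' Extract the full trait panel from a segmented root crown
#'
#' Runs the whole measurement stack on one binary volume: skeletonization
#' and skeleton traits, whole-crown geometry, fractal dimensions, vertical
#' profiles with their distribution statistics, per-slab solidity bins and
#' radial compactness. Values are reported in the registry's physical
#' units; traits that cannot be computed on a degenerate sample are `NA`
#' with the reason recorded in the `flags` attribute.
#'
#' @param mask A nonempty [binary_volume()].
#' @param sample_id Identifier stored in the first column.
#' @param n_slabs Vertical bins for the distribution traits (default 20;
#'   the registry's per-slab solidity columns assume the default).
#' @param n_shells Radial shells (default 9, matching the registry).
#' @param skel Optional precomputed [skeletonize()] result.
#' @param ... Passed to [skeletonize()].
#' @return One-row data frame: `sample_id` plus the 71 registered traits,
#'   with a `flags` attribute (named character vector of skip reasons).
#' @export
extract_traits <- function(mask, sample_id = "sample", n_slabs = 20L,
                           n_shells = 9L, skel = NULL, ...) {
  flags <- character(0)
  vals <- stats::setNames(rep(NA_real_, length(trait_names())), trait_names())

  if (is.null(skel)) skel <- skeletonize(mask, ...)
  sk <- skeleton_traits(skel, mask)
  vs <- volume_and_surface(mask)
  ch <- convex_hull_traits(mask)
  if (is.na(ch$Solidity)) flags <- c(flags, hull = "degenerate_coplanar_hull")
  ex <- extent_traits(mask)
  rc <- slice_root_counts(mask)
  fd_side <- fractal_dimension(mask, "side")
  fd_top <- fractal_dimension(mask, "top")
  if (is.na(fd_side) || is.na(fd_top))
    flags <- c(flags, fractal = "projection_smaller_than_4x4")

  for (nm in names(sk)) vals[nm] <- sk[[nm]]
  vals["Volume"] <- vs$Volume
  vals["SurfaceArea"] <- vs$SurfaceArea
  vals["ConvexHullVolume"] <- ch$ConvexHullVolume
  vals["Solidity"] <- ch$Solidity
  for (nm in names(ex)) vals[nm] <- ex[[nm]]
  for (nm in names(rc)) vals[nm] <- rc[[nm]]
  vals["FractalDimensionSide"] <- fd_side
  vals["FractalDimensionTop"] <- fd_top

  prof <- vertical_profile(mask, n_slabs)
  if (!is.na(prof$flag)) {
    flags <- c(flags, profile = prof$flag)
  } else {
    fam <- list(Biomass = prof$biomass, ConvexHull = prof$hull_area_cm2,
                Solidity = prof$solidity)
    for (f in names(fam)) {
      v <- fam[[f]]
      st <- distribution_stats(v[!is.na(v)])
      for (s in names(st))
        vals[paste0(f, tools::toTitleCase(s))] <- st[[s]]
    }
    if (n_slabs == 20L) {
      vals[sprintf("SolidityVHist%02d", seq_len(20L))] <- prof$solidity
    } else {
      flags <- c(flags, vhist = "n_slabs_differs_from_registry")
    }
  }
  ds <- density_s(mask, n_shells)
  if (n_shells == 9L) vals[names(ds)] <- ds
  else flags <- c(flags, density = "n_shells_differs_from_registry")

  out <- data.frame(sample_id = sample_id, t(vals), check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "flags") <- flags
  out
}
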