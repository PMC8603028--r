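#' @useDynLib rootcrown, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Volume metadata
#'
#' Describes the geometry of a reconstructed CT volume: voxel counts per
#' axis, the edge length of one (cubic) voxel in micrometres, the sample
#' bit depth and the byte order of the RAW encoding. Industrial CT export
#' is headerless, so this record travels in a small YAML sidecar next to
#' the `.raw` file.
#'
#' @param nx,ny,nz Voxel counts along x (within-slice fast axis), y
#'   (within-slice slow axis) and z (vertical axis; slice 1 is the top of
#'   the crown, i.e. the stem end).
#' @param voxel_size_um Edge length of one cubic voxel in micrometres.
#'   Typical bench-top root crown scans resolve 100-120 um.
#' @param bit_depth 8 or 16.
#' @param byte_order `"little"` or `"big"`; only meaningful for 16-bit data.
#' @return An object of class `volume_meta`.
#' @export
volume_meta <- function(nx, ny, nz, voxel_size_um, bit_depth = 16,
                        byte_order = c("little", "big")) {
  byte_order <- match.arg(byte_order)
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 1L)) stop("nx, ny, nz must all be >= 1")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel_size_um must be a positive number")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(
    list(nx = nx, ny = ny, nz = nz,
         voxel_size_um = as.numeric(voxel_size_um),
         bit_depth = as.integer(bit_depth), byte_order = byte_order),
    class = "volume_meta")
}

#' @export
print.volume_meta <- function(x, ...) {
  cat(sprintf("<volume_meta> %d x %d x %d voxels, %.1f um/voxel, %d-bit %s-endian\n",
              x$nx, x$ny, x$nz, x$voxel_size_um, x$bit_depth, x$byte_order))
  invisible(x)
}

new_voxel_volume <- function(data, meta) {
  stopifnot(inherits(meta, "volume_meta"),
            identical(dim(data), c(meta$nx, meta$ny, meta$nz)))
  structure(list(data = data, meta = meta), class = "voxel_volume")
}

#' Construct a grayscale voxel volume
#'
#' @param data Integer array of dim `c(nx, ny, nz)` (x fastest, z vertical;
#'   slice `[, , 1]` is the top of the crown).
#' @param meta A [volume_meta()] matching `dim(data)`.
#' @return A `voxel_volume`.
#' @export
voxel_volume <- function(data, meta) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 2^meta$bit_depth - 1)
    stop("intensities outside the bit-depth range")
  new_voxel_volume(data, meta)
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume>\n"); print(x$meta)
  cat(sprintf("  intensity range [%d, %d]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary (root vs air) volume
#'
#' @param mask Logical array of dim `c(nx, ny, nz)`.
#' @param meta A [volume_meta()].
#' @param provenance Optional list recording how the mask was produced.
#' @return A `binary_volume`.
#' @export
binary_volume <- function(mask, meta, provenance = list()) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3D array")
  stopifnot(identical(dim(mask), c(meta$nx, meta$ny, meta$nz)))
  structure(list(mask = mask, meta = meta, provenance = provenance),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat("<binary_volume>\n"); print(x$meta)
  cat(sprintf("  %d root voxels (%.3f%% of grid)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")
}

#' Read or write the YAML metadata sidecar of a RAW volume
#'
#' The sidecar has the same basename as the `.raw` file with extension
#' `.meta.yaml` and keys `nx`, `ny`, `nz`, `voxel_size_um`, `bit_depth`,
#' `byte_order`.
#'
#' @param path Path of the RAW file (or of the sidecar itself).
#' @return A [volume_meta()].
#' @export
read_volume_meta <- function(path) {
  sp <- if (grepl("\\.meta\\.yaml$", path)) path else sidecar_path(path)
  if (!file.exists(sp)) stop("metadata sidecar not found: ", sp)
  m <- yaml::read_yaml(sp)
  volume_meta(m$nx, m$ny, m$nz, m$voxel_size_um, m$bit_depth,
              if (is.null(m$byte_order)) "little" else m$byte_order)
}

#' @rdname read_volume_meta
#' @param meta A [volume_meta()] to serialize.
#' @export
write_volume_meta <- function(meta, path) {
  sp <- if (grepl("\\.meta\\.yaml$", path)) path else sidecar_path(path)
  yaml::write_yaml(unclass(meta), sp)
  invisible(sp)
}

#' Read a headerless RAW CT volume
#'
#' The file must contain exactly `nx * ny * nz * bit_depth/8` bytes, stored
#' x-fastest, then y, then z; slice z = 1 is the top (stem end) of the
#' crown. Reading and [write_raw_volume()] are exact inverses.
#'
#' @param path RAW file path.
#' @param meta A [volume_meta()]; if missing, the YAML sidecar next to
#'   `path` is read.
#' @return A [voxel_volume()].
#' @export
read_raw_volume <- function(path, meta = NULL) {
  if (is.null(meta)) meta <- read_volume_meta(path)
  nvox <- meta$nx * meta$ny * meta$nz
  bytes_per <- meta$bit_depth / 8L
  expected <- nvox * bytes_per
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop(sprintf("RAW size mismatch for %s: expected %d bytes (%d x %d x %d x %d), found %s",
                 path, expected, meta$nx, meta$ny, meta$nz, bytes_per,
                 ifelse(is.na(actual), "missing file", format(actual))))
  raw <- readBin(path, "raw", n = expected)
  if (meta$bit_depth == 8L) {
    v <- as.integer(raw)
  } else {
    lo_first <- meta$byte_order == "little"
    m <- matrix(as.integer(raw), nrow = 2L)
    v <- if (lo_first) m[1L, ] + 256L * m[2L, ] else m[2L, ] + 256L * m[1L, ]
  }
  voxel_volume(array(v, dim = c(meta$nx, meta$ny, meta$nz)), meta)
}

#' Write a voxel volume as headerless RAW plus sidecar
#'
#' @param vol A [voxel_volume()].
#' @param path Output `.raw` path; a `.meta.yaml` sidecar is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_raw_volume <- function(vol, path) {
  meta <- vol$meta
  v <- as.integer(vol$data)
  if (meta$bit_depth == 8L) {
    raw <- as.raw(v)
  } else {
    lo <- as.raw(v %% 256L); hi <- as.raw(v %/% 256L)
    raw <- vector("raw", 2L * length(v))
    if (meta$byte_order == "little") {
      raw[c(TRUE, FALSE)] <- lo; raw[c(FALSE, TRUE)] <- hi
    } else {
      raw[c(TRUE, FALSE)] <- hi; raw[c(FALSE, TRUE)] <- lo
    }
  }
  writeBin(raw, path)
  write_volume_meta(meta, path)
  invisible(path)
}

#' Export a volume as a stack of grayscale slice images
#'
#' One lossless image per z index, named `slice_0000.tif` (or `.png` for
#' 8-bit data when `format = "png"`) so that lexical order equals z order.
#' [read_slice_stack()] reconstructs the volume exactly.
#'
#' @param vol A [voxel_volume()].
#' @param out_dir Output directory (created if needed).
#' @param format `"tiff"` (8- or 16-bit) or `"png"` (8-bit only).
#' @param overwrite Refuse to clobber existing slice files unless `TRUE`.
#' @return Character vector of files written, invisibly.
#' @export
volume_to_slices <- function(vol, out_dir, format = c("tiff", "png"),
                             overwrite = FALSE) {
  format <- match.arg(format)
  meta <- vol$meta
  if (format == "png" && meta$bit_depth != 8L)
    stop("png slices support 8-bit volumes only; use format = \"tiff\"")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "png") "png" else "tif"
  files <- file.path(out_dir, sprintf("slice_%04d.%s", seq_len(meta$nz) - 1L, ext))
  if (!overwrite && any(file.exists(files)))
    stop("slice files already exist in ", out_dir, "; set overwrite = TRUE")
  maxval <- 2^meta$bit_depth - 1
  for (z in seq_len(meta$nz)) {
    img <- t(vol$data[, , z]) / maxval   # rows = y, cols = x
    if (format == "png") {
      png::writePNG(img, files[z])
    } else {
      tiff::writeTIFF(img, files[z], bits.per.sample = meta$bit_depth,
                      compression = "none")
    }
  }
  write_volume_meta(meta, file.path(out_dir, "stack.meta.yaml"))
  invisible(files)
}

#' Read a slice stack back into a voxel volume
#'
#' @param dir Directory of slice images written by [volume_to_slices()] (or
#'   any stack of equally-sized grayscale images whose lexical order is z
#'   order, top slice first).
#' @param meta Optional [volume_meta()]; defaults to the `stack.meta.yaml`
#'   saved with the stack.
#' @return A [voxel_volume()].
#' @export
read_slice_stack <- function(dir, meta = NULL) {
  if (is.null(meta)) meta <- read_volume_meta(file.path(dir, "stack.meta.yaml"))
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE))
  if (length(files) != meta$nz)
    stop(sprintf("expected %d slices in %s, found %d", meta$nz, dir, length(files)))
  maxval <- 2^meta$bit_depth - 1
  data <- array(0L, dim = c(meta$nx, meta$ny, meta$nz))
  for (z in seq_along(files)) {
    img <- if (grepl("\\.png$", files[z])) png::readPNG(files[z])
           else tiff::readTIFF(files[z])
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    data[, , z] <- as.integer(round(t(img) * maxval))
  }
  voxel_volume(data, meta)
}

#' Physical coordinates of root voxels
#'
#' Voxel `(i, j, k)` (1-based) has its centre at
#' `(i - 0.5, j - 0.5, k - 0.5) * voxel_size_um`, i.e. half-integer physical
#' coordinates on a 0-based grid — symmetric under axis flips.
#'
#' @param mask A [binary_volume()].
#' @return Matrix with columns `x`, `y`, `z` in micrometres.
#' @export
voxel_coordinates_um <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  colnames(idx) <- c("x", "y", "z")
  (idx - 0.5) * mask$meta$voxel_size_um
}

#' Export the root mask as a point cloud
#'
#' One point per root voxel at its physical centre (micrometres). OBJ files
#' use `v x y z` lines; XYZ files are whitespace-separated triples.
#'
#' @param mask A [binary_volume()]; must be nonempty.
#' @param path Output file.
#' @param format `"obj"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(mask, path, format = c("obj", "xyz")) {
  format <- match.arg(format)
  if (!any(mask$mask)) stop("mask is empty; nothing to export")
  xyz <- voxel_coordinates_um(mask)
  lines <- if (format == "obj")
    sprintf("v %.6g %.6g %.6g", xyz[, 1], xyz[, 2], xyz[, 3])
  else
    sprintf("%.6g %.6g %.6g", xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ/OBJ point cloud written by [write_point_cloud()]
#'
#' @param path File path.
#' @return Numeric matrix with columns `x`, `y`, `z` (micrometres).
#' @export
read_point_cloud <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1], "v "))
    lines <- sub("^v ", "", lines)
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  colnames(m) <- c("x", "y", "z")
  m
}
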