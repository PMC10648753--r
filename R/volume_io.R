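# Voxel volume container and I/O for headerless RAW + sidecar and slice
# stacks.
#
# Conventions (fixed throughout the package):
#   * volumes are 3D integer arrays indexed [x, y, z], x fastest-varying,
#     which matches both R's column-major storage and the on-disk RAW order;
#   * voxel indices are 0-based in all user-facing coordinates (crop boxes,
#     ROI centers) with half-open [lo, hi) boxes;
#   * the center of voxel i lies at (i + 0.5) * spacing_mm along each axis.

#' Volume metadata
#'
#' Describes the geometry and grayscale model of a CT volume: grid shape,
#' physical voxel spacing, the signed-16-bit grayscale range, and the byte
#' order of the on-disk RAW representation.
#'
#' @param shape Integer triple `(nx, ny, nz)`, all >= 1.
#' @param spacing_mm Positive voxel spacing in mm; a scalar is recycled to an
#'   isotropic triple. Default 0.160 mm.
#' @param gsv_min,gsv_max Inclusive grayscale bounds; defaults are the full
#'   signed 16-bit range.
#' @param byte_order `"little"` or `"big"`; byte order of RAW files.
#' @return An object of class `volume_meta`.
#' @export
volume_meta <- function(shape, spacing_mm = 0.160,
                        gsv_min = -32768L, gsv_max = 32767L,
                        byte_order = "little") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive reals")
  gsv_min <- as.integer(gsv_min); gsv_max <- as.integer(gsv_max)
  if (gsv_min >= gsv_max) stop("'gsv_min' must be < 'gsv_max'")
  byte_order <- match.arg(byte_order, c("little", "big"))
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 gsv_min = gsv_min, gsv_max = gsv_max,
                 byte_order = byte_order),
            class = "volume_meta")
}

#' @export
print.volume_meta <- function(x, ...) {
  cat(sprintf("CT volume metadata: %d x %d x %d voxels, spacing %s mm, GSV [%d, %d], %s-endian\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing_mm), collapse = " x "),
              x$gsv_min, x$gsv_max, x$byte_order))
  invisible(x)
}

#' Voxel volume
#'
#' A 3D grid of integer grayscale values (GSVs) with its metadata. GSVs are
#' proportional to X-ray attenuation, hence local density.
#'
#' @param values 3D integer array, dimensions equal to `meta$shape`.
#' @param meta A [volume_meta()]; if omitted, built from `dim(values)` and
#'   `spacing_mm`.
#' @param spacing_mm Used only when `meta` is missing.
#' @return An object of class `voxel_volume` with elements `values` and
#'   `meta`.
#' @export
voxel_volume <- function(values, meta = NULL, spacing_mm = 0.160) {
  if (length(dim(values)) != 3L) stop("'values' must be a 3D array")
  if (is.null(meta)) meta <- volume_meta(dim(values), spacing_mm)
  if (!inherits(meta, "volume_meta")) stop("'meta' must be a volume_meta")
  if (!all(dim(values) == meta$shape))
    stop(sprintf("value dimensions (%s) do not match meta shape (%s)",
                 paste(dim(values), collapse = "x"),
                 paste(meta$shape, collapse = "x")))
  storage.mode(values) <- "integer"
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < meta$gsv_min || rng[2] > meta$gsv_max)
    stop(sprintf("values [%d, %d] outside GSV range [%d, %d]",
                 rng[1], rng[2], meta$gsv_min, meta$gsv_max))
  structure(list(values = values, meta = meta), class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Voxel volume: %d x %d x %d voxels (%.1f x %.1f x %.1f mm), GSV range observed [%d, %d]\n",
              m$shape[1], m$shape[2], m$shape[3],
              m$shape[1] * m$spacing_mm[1], m$shape[2] * m$spacing_mm[2],
              m$shape[3] * m$spacing_mm[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

voxel_volume_mm3 <- function(meta) prod(meta$spacing_mm)

#' Read a headerless RAW volume
#'
#' Reads 16-bit signed integers in raster order (x fastest, then y, then z).
#'
#' @param path RAW file path.
#' @param meta A [volume_meta()], or the path of a sidecar file written by
#'   [write_raw()].
#' @return A [voxel_volume()].
#' @export
read_raw <- function(path, meta) {
  if (is.character(meta)) meta <- read_sidecar(meta)
  if (!file.exists(path)) stop("cannot read '", path, "'")
  expected <- prod(meta$shape) * 2
  actual <- file.size(path)
  if (actual != expected)
    stop(sprintf("RAW size mismatch for '%s': expected %d bytes (%s x 2), got %d",
                 path, expected, paste(meta$shape, collapse = "x"), actual))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "integer", n = prod(meta$shape), size = 2L,
               signed = TRUE, endian = meta$byte_order)
  voxel_volume(array(v, dim = meta$shape), meta)
}

#' Write a headerless RAW volume with a plain-text sidecar
#'
#' @param volume A [voxel_volume()].
#' @param path Destination RAW path; the sidecar is written at
#'   `paste0(path, ".meta")`.
#' @return The sidecar path, invisibly.
#' @export
write_raw <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  m <- volume$meta
  con <- file(path, "wb")
  writeBin(as.integer(volume$values), con, size = 2L, endian = m$byte_order)
  close(con)
  sidecar <- paste0(path, ".meta")
  writeLines(c(
    sprintf("shape: %s", paste(m$shape, collapse = " ")),
    sprintf("spacing_mm: %s", paste(format(m$spacing_mm, digits = 12), collapse = " ")),
    "dtype: int16",
    sprintf("byte_order: %s", m$byte_order),
    sprintf("gsv_range: %d %d", m$gsv_min, m$gsv_max),
    "axis_order: x fastest"), sidecar)
  invisible(sidecar)
}

#' Read a sidecar metadata file
#' @param path Sidecar path (as written by [write_raw()]).
#' @return A [volume_meta()].
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path)
  get <- function(key, default = NULL) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) == 0L) return(default)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  shape <- as.integer(strsplit(get("shape"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("spacing_mm", "0.16 0.16 0.16"), "\\s+")[[1]])
  gsv <- as.integer(strsplit(get("gsv_range", "-32768 32767"), "\\s+")[[1]])
  volume_meta(shape, spacing, gsv[1], gsv[2], get("byte_order", "little"))
}

#' Read a stack of 2D grayscale slices as a volume
#'
#' Lexicographic filename order defines the z (slice) axis. TIFF slices are
#' read with their native integer values; PNG slices are rescaled from
#' \[0, 1\] to the stored integer depth (8- or 16-bit, detected from the
#' values). Image rows map to the y axis and columns to x.
#'
#' @param directory Directory containing the slices.
#' @param spacing_mm Voxel spacing (scalar or triple).
#' @param pattern Filename filter, by default TIFF and PNG extensions.
#' @return A [voxel_volume()].
#' @export
read_slice_stack <- function(directory, spacing_mm = 0.160,
                             pattern = "\\.(tif|tiff|png)$") {
  files <- sort(list.files(directory, pattern = pattern, ignore.case = TRUE,
                           full.names = TRUE), method = "radix")
  if (length(files) == 0L) stop("no slice images found in '", directory, "'")
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      v8 <- img * 255
      if (max(abs(v8 - round(v8))) < 1e-6) img <- round(v8)
      else img <- round(img * 65535)
    } else {
      img <- tiff::readTIFF(f, as.is = TRUE)
      if (length(dim(img)) == 3L) img <- img[, , 1]
    }
    img
  }
  first <- read_one(files[1])
  ny <- nrow(first); nx <- ncol(first)
  vol <- array(0L, dim = c(nx, ny, length(files)))
  for (k in seq_along(files)) {
    img <- read_one(files[k])
    if (nrow(img) != ny || ncol(img) != nx)
      stop(sprintf("slice '%s' is %dx%d; expected %dx%d",
                   basename(files[k]), nrow(img), ncol(img), ny, nx))
    vol[, , k] <- as.integer(t(img))
  }
  voxel_volume(vol, volume_meta(dim(vol), spacing_mm))
}

#' Crop a volume
#'
#' Extracts the half-open box `[lo, hi)` given in 0-based voxel indices.
#'
#' @param volume A [voxel_volume()].
#' @param lo,hi Integer triples, `0 <= lo < hi <= shape` per axis.
#' @return The cropped [voxel_volume()]; spacing is preserved.
#' @export
crop_volume <- function(volume, lo, hi) {
  stopifnot(inherits(volume, "voxel_volume"))
  lo <- as.integer(lo); hi <- as.integer(hi)
  shp <- volume$meta$shape
  if (length(lo) != 3L || length(hi) != 3L)
    stop("'lo' and 'hi' must be integer triples")
  if (any(lo < 0L) || any(hi > shp) || any(lo >= hi))
    stop(sprintf("crop box [%s, %s) out of bounds for shape %s",
                 paste(lo, collapse = ","), paste(hi, collapse = ","),
                 paste(shp, collapse = "x")))
  vals <- volume$values[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                        (lo[3] + 1):hi[3], drop = FALSE]
  m <- volume$meta
  voxel_volume(vals, volume_meta(hi - lo, m$spacing_mm, m$gsv_min, m$gsv_max,
                                 m$byte_order))
}
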