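# Per-pore and per-sample morphometry: volume, isosurface area, Feret
# length/width, equivalent diameter, porosity, sample volume, pore-size
# distribution, and local cubic-ROI analysis.

#' Deterministic quasi-uniform direction set for Feret measurements
#'
#' The three coordinate axes plus a Fibonacci-spiral hemisphere sampling
#' (directions are taken up to sign, so a hemisphere suffices). The set is
#' fixed and deterministic, so Feret extents are reproducible.
#'
#' @param n Number of spiral directions, >= 125; default 128 (plus 3 axes).
#' @return A 3 x (n + 3) matrix of unit direction vectors.
#' @export
feret_directions <- function(n = 128L) {
  n <- as.integer(n)
  i <- seq_len(n) - 0.5
  z <- i / n                       # hemisphere z in (0, 1)
  phi <- i * pi * (3 - sqrt(5))    # golden angle
  r <- sqrt(1 - z^2)
  d <- rbind(r * cos(phi), r * sin(phi), z)
  cbind(diag(3), d)
}

# voxel corner points (mm) of the given 0-based voxel coordinates; corners
# rather than centers so a single voxel has nonzero extent
voxel_corners <- function(coords0, spacing) {
  shifts <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  out <- matrix(0, nrow = nrow(coords0) * 8L, ncol = 3L)
  for (k in 1:8) {
    rows <- seq_len(nrow(coords0)) + (k - 1L) * nrow(coords0)
    out[rows, ] <- sweep(coords0 + matrix(shifts[k, ], nrow(coords0), 3,
                                          byrow = TRUE), 2, spacing, "*")
  }
  out
}

feret_extents <- function(points_mm, dirs) {
  proj <- points_mm %*% dirs
  ext <- apply(proj, 2, function(p) max(p) - min(p))
  c(length = max(ext), width = min(ext))
}

#' Measure labeled pores
#'
#' Per label: volume as voxel count times voxel volume (exact for voxel
#' sets); surface area as the triangulated 0.5-level isosurface of a
#' corner-averaged indicator field (labels too thin to support that surface
#' fall back to exposed-face counting); Feret length and width as the
#' max/min directional extent of the label's voxel corner points over the
#' fixed direction set; equivalent diameter by the closed form
#' `(6 V / pi)^(1/3)`; plus the centroid (mm) and a border-touching flag.
#'
#' @param labels A [label_map()].
#' @param spacing_mm Voxel spacing; defaults to the label map's.
#' @param directions Direction matrix from [feret_directions()].
#' @param area_method `"isosurface"` (default) or `"faces"` (exposed voxel
#'   faces, a debug alternative biased high for smooth blobs).
#' @return A data.frame of class `pore_stats`, one row per label: `label`,
#'   `volume_mm3`, `area_mm2`, `eq_diameter_mm`, `length_mm`, `width_mm`,
#'   `centroid_x/y/z_mm`, `touches_border`.
#' @export
measure_labels <- function(labels, spacing_mm = NULL,
                           directions = feret_directions(),
                           area_method = c("isosurface", "faces")) {
  stopifnot(inherits(labels, "label_map"))
  area_method <- match.arg(area_method)
  s <- if (is.null(spacing_mm)) labels$spacing_mm else rep(spacing_mm, length.out = 3)
  empty <- data.frame(label = integer(0), volume_mm3 = numeric(0),
                      area_mm2 = numeric(0), eq_diameter_mm = numeric(0),
                      length_mm = numeric(0), width_mm = numeric(0),
                      centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
                      centroid_z_mm = numeric(0), touches_border = logical(0))
  class(empty) <- c("pore_stats", "data.frame")
  if (labels$n_labels == 0L) return(empty)
  g <- labels$grid
  shp <- dim(g)
  vox_mm3 <- prod(s)
  bb <- cpp_label_bbox(as.integer(g), shp, labels$n_labels)
  rows <- vector("list", labels$n_labels)
  for (l in seq_len(labels$n_labels)) {
    cnt <- bb[l, 1]
    lo <- bb[l, c(2, 4, 6)]; hi <- bb[l, c(3, 5, 7)]
    sub <- g[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
             (lo[3] + 1):(hi[3] + 1), drop = FALSE] == l
    dim(sub) <- hi - lo + 1L
    area <- if (area_method == "isosurface") {
      a <- cpp_mt_area(as.logical(sub), dim(sub), s)
      if (a <= 0) cpp_face_area(as.logical(sub), dim(sub), s) else a
    } else {
      cpp_face_area(as.logical(sub), dim(sub), s)
    }
    idx <- which(sub)
    co <- arrayInd(idx, dim(sub)) - 1L          # 0-based within bbox
    # surface voxels are enough for Feret extents (extremes are on the hull)
    surf <- surface_voxels(sub, co)
    co_g <- sweep(surf, 2, lo, "+")             # 0-based global
    fer <- feret_extents(voxel_corners(co_g, s), directions)
    centroid <- (colMeans(sweep(co, 2, lo, "+")) + 0.5) * s
    vol <- cnt * vox_mm3
    rows[[l]] <- data.frame(
      label = l, volume_mm3 = vol, area_mm2 = area,
      eq_diameter_mm = (6 * vol / pi)^(1 / 3),
      length_mm = fer["length"], width_mm = fer["width"],
      centroid_x_mm = centroid[1], centroid_y_mm = centroid[2],
      centroid_z_mm = centroid[3],
      touches_border = any(lo == 0L) || any(hi == shp - 1L))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pore_stats", "data.frame")
  out
}

# 0-based coords of voxels with at least one 6-neighbor outside the set
surface_voxels <- function(sub, co) {
  d <- dim(sub)
  at <- function(x, y, z) {
    ok <- x >= 0 & y >= 0 & z >= 0 & x < d[1] & y < d[2] & z < d[3]
    v <- logical(length(x))
    v[ok] <- sub[cbind(x[ok], y[ok], z[ok]) + 1L]
    v
  }
  interior <- rep(TRUE, nrow(co))
  for (k in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nb <- co
      nb[, k] <- nb[, k] + sgn
      interior <- interior & at(nb[, 1], nb[, 2], nb[, 3])
      if (!any(interior)) break
    }
  }
  co[!interior, , drop = FALSE]
}

#' Porosity of a pore phase within a sample
#'
#' `100 * pore voxel count / sample voxel count`. Pore voxels outside the
#' sample violate the expected nesting; they are reported and clipped.
#'
#' @param pores,sample [voxel_mask()]s of identical shape.
#' @return Porosity in percent.
#' @export
porosity <- function(pores, sample) {
  stopifnot(inherits(pores, "voxel_mask"), inherits(sample, "voxel_mask"))
  if (!all(dim(pores$grid) == dim(sample$grid))) stop("mask shapes differ")
  n_sample <- sum(sample$grid)
  if (n_sample == 0L) stop("empty sample mask: porosity undefined")
  stray <- sum(pores$grid & !sample$grid)
  if (stray > 0)
    message(sprintf("porosity: %d pore voxels outside the sample (clipped)", stray))
  100 * sum(pores$grid & sample$grid) / n_sample
}

#' Per-sample morphometry summary
#'
#' Arithmetic means of the per-pore parameters, plus porosity, sample
#' volume (`filled voxel count x voxel volume / 1000`, in mL) and pore
#' count. With zero pores the means are `NA` and porosity 0.
#'
#' @param stats A `pore_stats` data.frame from [measure_labels()].
#' @param pores,sample [voxel_mask()]s (the recovered pore phase and the
#'   filled whole-sample mask).
#' @param drop_border_pores Exclude border-touching pores from the means
#'   (they are measured but flagged); default `FALSE`.
#' @return An object of class `morphometry_summary`.
#' @export
summarize_morphometry <- function(stats, pores, sample,
                                  drop_border_pores = FALSE) {
  stopifnot(inherits(sample, "voxel_mask"))
  st <- stats
  if (drop_border_pores && nrow(st) > 0) st <- st[!st$touches_border, , drop = FALSE]
  vox_mm3 <- prod(sample$spacing_mm)
  n <- nrow(st)
  mean_or_na <- function(x) if (n > 0) mean(x) else NA_real_
  structure(list(
    pore_count = n,
    mean_volume_mm3 = mean_or_na(st$volume_mm3),
    mean_area_mm2 = mean_or_na(st$area_mm2),
    mean_length_mm = mean_or_na(st$length_mm),
    mean_width_mm = mean_or_na(st$width_mm),
    mean_eq_diameter_mm = mean_or_na(st$eq_diameter_mm),
    porosity_pct = if (sum(pores$grid) == 0) 0 else porosity(pores, sample),
    sample_volume_mL = sum(sample$grid) * vox_mm3 / 1000),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("Morphometry: %d pores, porosity %.2f%%, sample %.2f mL\n",
              x$pore_count, x$porosity_pct, x$sample_volume_mL))
  cat(sprintf("  mean pore: volume %.3f mm^3, area %.3f mm^2, length %.3f mm, width %.3f mm\n",
              x$mean_volume_mm3, x$mean_area_mm2, x$mean_length_mm,
              x$mean_width_mm))
  invisible(x)
}

#' @export
as.data.frame.morphometry_summary <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Pore-size distribution by equivalent diameter
#'
#' Half-open bins `[lo, hi)` on `eq_diameter_mm`; pores at or above the
#' last edge are collected in a reported overflow bin. Percentages are over
#' all pores (bins plus overflow) and sum to 100.
#'
#' @param stats A `pore_stats` data.frame.
#' @param bin_edges_mm Increasing bin edges, default `c(0, 2, 4, 6, 8, 10)`.
#' @return An object of class `size_distribution`: a data.frame with
#'   `bin_lo_mm`, `bin_hi_mm` (`Inf` for the overflow row), `count`,
#'   `percentage`.
#' @export
size_distribution <- function(stats, bin_edges_mm = c(0, 2, 4, 6, 8, 10)) {
  if (is.unsorted(bin_edges_mm, strictly = TRUE))
    stop("'bin_edges_mm' must be strictly increasing")
  d <- stats$eq_diameter_mm
  k <- length(bin_edges_mm) - 1L
  idx <- findInterval(d, bin_edges_mm)          # 0 below, k+1 at/after last
  counts <- tabulate(idx[idx >= 1L & idx <= k], nbins = k)
  overflow <- sum(idx > k)
  total <- length(d)
  out <- data.frame(bin_lo_mm = c(bin_edges_mm[-(k + 1L)], bin_edges_mm[k + 1L]),
                    bin_hi_mm = c(bin_edges_mm[-1L], Inf),
                    count = c(counts, overflow))
  out$percentage <- if (total > 0) 100 * out$count / total else 0
  class(out) <- c("size_distribution", "data.frame")
  out
}

#' @export
plot.size_distribution <- function(x, ...) {
  lab <- ifelse(is.finite(x$bin_hi_mm),
                sprintf("%g-%g", x$bin_lo_mm, x$bin_hi_mm),
                sprintf(">=%g", x$bin_lo_mm))
  graphics::barplot(x$count, names.arg = lab, xlab = "EqDiameter (mm)",
                    ylab = "pore count", ...)
  invisible(x)
}

#' Extract a cubic local ROI
#'
#' A `side_vox`^3 subvolume centered at a 0-based voxel coordinate, used
#' for local grayscale analysis of named bread regions (center, crumb,
#' skin). The cube must lie fully inside the volume.
#'
#' @param volume A [voxel_volume()].
#' @param center_vox 0-based integer triple.
#' @param side_vox Cube side in voxels, default 45.
#' @return A [voxel_volume()] of shape `side_vox`^3.
#' @export
extract_cube_roi <- function(volume, center_vox, side_vox = 45L) {
  stopifnot(inherits(volume, "voxel_volume"))
  side_vox <- as.integer(side_vox)
  center_vox <- as.integer(center_vox)
  lo <- center_vox - side_vox %/% 2L
  hi <- lo + side_vox
  shp <- volume$meta$shape
  for (k in 1:3) {
    if (lo[k] < 0L || hi[k] > shp[k])
      stop(sprintf("ROI cube [%d, %d) exceeds volume bounds on axis %s (size %d)",
                   lo[k], hi[k], c("x", "y", "z")[k], shp[k]))
  }
  crop_volume(volume, lo, hi)
}

#' Local pore fraction of a cubic ROI
#'
#' Percentage of ROI voxels whose GSV lies in the pore band (closed
#' interval), by default -1250..-1000.
#'
#' @param cube A [voxel_volume()] (typically from [extract_cube_roi()]).
#' @param lo,hi Pore band bounds.
#' @return Percentage in \[0, 100\].
#' @export
local_pore_fraction <- function(cube, lo = -1250, hi = -1000) {
  stopifnot(inherits(cube, "voxel_volume"))
  if (lo > hi) stop("'lo' must be <= 'hi'")
  100 * mean(cube$values >= lo & cube$values <= hi)
}

#' Write a per-pore table as CSV
#' @param stats A `pore_stats` data.frame; column units are in the names.
#' @param path Output path.
#' @export
write_pore_stats <- function(stats, path) {
  write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
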