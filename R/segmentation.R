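# Segmentation chain: histogramming, balanced histogram thresholding, band
# thresholding, hole filling, mask arithmetic, ball opening,
# connected-component labeling.
#
# The pore-recovery chain mirrors standard CT practice for closed-cell
# foams: threshold the solid matrix by its grayscale band, fill enclosed
# cavities to recover the whole sample, subtract the matrix to isolate the
# interior pore phase, open with a ball to cut necks between coalesced
# pores, then label the separated pores.

#' Binary voxel mask
#'
#' @param grid 3D logical array.
#' @param spacing_mm Voxel spacing (scalar or triple).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(grid, spacing_mm = 0.160) {
  if (length(dim(grid)) != 3L) stop("'grid' must be a 3D array")
  storage.mode(grid) <- "logical"
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  structure(list(grid = grid, spacing_mm = as.numeric(spacing_mm)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("Binary mask: %s voxels, %d foreground (%.2f%%)\n",
              paste(dim(x$grid), collapse = " x "), sum(x$grid),
              100 * mean(x$grid)))
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$grid)

#' Label map of connected components
#'
#' @param grid 3D integer array; 0 is background, foreground labels are
#'   exactly `1..n_labels`.
#' @param n_labels Number of labels.
#' @param spacing_mm Voxel spacing.
#' @return An object of class `label_map`.
#' @export
label_map <- function(grid, n_labels, spacing_mm = 0.160) {
  if (length(dim(grid)) != 3L) stop("'grid' must be a 3D array")
  storage.mode(grid) <- "integer"
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  structure(list(grid = grid, n_labels = as.integer(n_labels),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("Label map: %s voxels, %d components\n",
              paste(dim(x$grid), collapse = " x "), x$n_labels))
  invisible(x)
}

as_grid <- function(x) {
  if (inherits(x, "voxel_mask")) x$grid
  else if (inherits(x, "voxel_volume")) x$values
  else x
}

#' Grayscale histogram of a volume
#'
#' Bins are half-open `[edge_i, edge_{i+1})` with integer edges aligned to
#' multiples of `bin_width`, covering the range of the included values.
#'
#' @param volume A [voxel_volume()].
#' @param bin_width Integer bin width >= 1 (GSV units).
#' @param region Optional [voxel_mask()] restricting the histogrammed voxels.
#' @return An object of class `gsv_histogram` with `bin_edges` and `counts`;
#'   counts sum to the number of histogrammed voxels.
#' @export
compute_histogram <- function(volume, bin_width = 10L, region = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  bin_width <- as.integer(bin_width)
  if (bin_width < 1L) stop("'bin_width' must be >= 1")
  v <- volume$values
  if (!is.null(region)) {
    g <- as_grid(region)
    if (!all(dim(g) == dim(v))) stop("region shape does not match volume")
    v <- v[g]
  }
  if (length(v) == 0L) stop("empty region: nothing to histogram")
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- floor(max(v) / bin_width) * bin_width + bin_width
  edges <- seq.int(lo, hi, by = bin_width)
  idx <- (as.numeric(v) - lo) %/% bin_width + 1
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = as.integer(edges), counts = as.integer(counts)),
            class = "gsv_histogram")
}

#' @export
print.gsv_histogram <- function(x, ...) {
  occ <- which(x$counts > 0)
  cat(sprintf("GSV histogram: %d bins of width %d over [%d, %d), %d voxels\n",
              length(x$counts), x$bin_edges[2] - x$bin_edges[1],
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              sum(x$counts)))
  cat(sprintf("  occupied: %d bins, modal bin [%d, %d)\n", length(occ),
              x$bin_edges[which.max(x$counts)],
              x$bin_edges[which.max(x$counts) + 1]))
  invisible(x)
}

#' @export
plot.gsv_histogram <- function(x, ...) {
  mids <- (x$bin_edges[-length(x$bin_edges)] + x$bin_edges[-1]) / 2
  graphics::plot(mids, x$counts, type = "h", xlab = "grayscale value",
                 ylab = "voxel count", ...)
  invisible(x)
}

#' Export a histogram as two-column delimited text
#' @param hist A `gsv_histogram`.
#' @param path Output path; columns are `bin_lower_edge` and `count`.
#' @export
write_histogram <- function(hist, path) {
  df <- data.frame(bin_lower_edge = hist$bin_edges[-length(hist$bin_edges)],
                   count = hist$counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Balanced histogram threshold
#'
#' Finds a bimodal split by balancing the histogram: the working range
#' starts at the outermost nonempty bins and the outer bin of the heavier
#' side is removed until the range collapses to a single bin. Weights are
#' taken about the real-valued center of the current range (a bin sitting
#' exactly on the center contributes half to each side). On an exact
#' balance tie both outer bins are removed; when only two tied bins remain
#' the right one is dropped, so the range collapses onto the left bin. The
#' threshold is the lower edge of the final bin.
#'
#' @param hist A `gsv_histogram` with at least one nonzero count.
#' @return The threshold GSV (lower edge of the final bin).
#' @export
balanced_histogram_threshold <- function(hist) {
  h <- as.numeric(hist$counts)
  nz <- which(h > 0)
  if (length(nz) == 0L) stop("all-zero histogram: no threshold defined")
  l <- nz[1]; r <- nz[length(nz)]
  while (r > l) {
    ctr <- (l + r) / 2
    below <- seq_len(floor(ctr) - l + 1) + l - 1        # bins l..floor(ctr)
    w_l <- sum(h[setdiff(below, ctr)])
    w_r <- sum(h[setdiff(seq.int(ceiling(ctr), r), ctr)])
    if (ctr == floor(ctr)) {                            # center bin splits
      w_l <- w_l + h[ctr] / 2
      w_r <- w_r + h[ctr] / 2
    }
    if (w_l > w_r) {
      l <- l + 1L
    } else if (w_r > w_l) {
      r <- r - 1L
    } else if (r - l >= 2L) {                           # balanced: trim both
      l <- l + 1L; r <- r - 1L
    } else {                                            # two tied bins
      r <- r - 1L
    }
  }
  hist$bin_edges[l]
}

#' Band threshold
#'
#' Marks voxels whose GSV lies in the closed interval `[lo, hi]`, optionally
#' restricted to a region. The matrix band of steamed-bread crumb is
#' typically -750..-250 and the pore/air band -1250..-1000.
#'
#' @param volume A [voxel_volume()].
#' @param lo,hi Band bounds, `lo <= hi`.
#' @param region Optional [voxel_mask()].
#' @return A [voxel_mask()].
#' @export
band_threshold <- function(volume, lo, hi, region = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (lo > hi) stop("'lo' must be <= 'hi'")
  g <- volume$values >= lo & volume$values <= hi
  if (!is.null(region)) {
    rg <- as_grid(region)
    if (!all(dim(rg) == dim(g))) stop("region shape does not match volume")
    g <- g & rg
  }
  voxel_mask(g, volume$meta$spacing_mm)
}

#' Fill enclosed cavities in a mask
#'
#' Background components not connected to any volume face (under the chosen
#' background connectivity) are set to foreground. The result is a superset
#' of the input and the operation is idempotent.
#'
#' @param mask A [voxel_mask()].
#' @param background_connectivity 6 (default) or 26; 6-connected background
#'   is the standard dual of 26-connected foreground.
#' @return The filled [voxel_mask()].
#' @export
fill_holes <- function(mask, background_connectivity = 6L) {
  stopifnot(inherits(mask, "voxel_mask"))
  conn <- as.integer(background_connectivity)
  if (!conn %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  g <- mask$grid
  reach <- cpp_background_reachable(as.logical(g), dim(g), conn)
  out <- g | !array(reach, dim(g))
  voxel_mask(out, mask$spacing_mm)
}

#' Mask difference (pore-phase recovery)
#'
#' `filled AND NOT matrix`: subtracting the solid matrix from the filled
#' whole-sample mask leaves the interior pore phase. Voxels of `matrix`
#' outside `filled` violate the expected nesting; they are counted, reported
#' via a message, and clipped.
#'
#' @param filled,matrix [voxel_mask()]s of identical shape.
#' @return A [voxel_mask()].
#' @export
mask_difference <- function(filled, matrix) {
  stopifnot(inherits(filled, "voxel_mask"), inherits(matrix, "voxel_mask"))
  if (!all(dim(filled$grid) == dim(matrix$grid)))
    stop("mask shapes differ")
  stray <- sum(matrix$grid & !filled$grid)
  if (stray > 0)
    message(sprintf("mask_difference: %d matrix voxels outside the filled mask (clipped)", stray))
  voxel_mask(filled$grid & !matrix$grid, filled$spacing_mm)
}

#' Offsets of a digitized Euclidean ball
#'
#' A voxel offset is included iff its center distance is <= `radius_vox`.
#'
#' @param radius_vox Ball radius in voxels, > 0.
#' @return Integer matrix of offsets (n x 3).
#' @export
ball_offsets <- function(radius_vox) {
  if (radius_vox <= 0) stop("'radius_vox' must be > 0")
  r <- floor(radius_vox)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= radius_vox^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Morphological opening with a ball structuring element
#'
#' Erosion followed by dilation with the same digitized Euclidean ball.
#' Anti-extensive (result is a subset of the input) and idempotent. Voxels
#' outside the grid count as background, so structures touching the volume
#' border are eroded there too.
#'
#' @param mask A [voxel_mask()].
#' @param ball_radius_vox Ball radius in voxels (radius, not diameter);
#'   default 3.
#' @return The opened [voxel_mask()].
#' @export
binary_opening <- function(mask, ball_radius_vox = 3.0) {
  stopifnot(inherits(mask, "voxel_mask"))
  off <- ball_offsets(ball_radius_vox)
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]   # center handled in C++
  g <- mask$grid
  er <- cpp_erode(as.logical(g), dim(g), off)
  di <- cpp_dilate(er, dim(g), off)
  voxel_mask(array(di, dim(g)), mask$spacing_mm)
}

#' Morphological erosion with a ball structuring element
#' @inheritParams binary_opening
#' @return The eroded [voxel_mask()].
#' @export
binary_erosion <- function(mask, ball_radius_vox = 3.0) {
  stopifnot(inherits(mask, "voxel_mask"))
  off <- ball_offsets(ball_radius_vox)
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  g <- mask$grid
  voxel_mask(array(cpp_erode(as.logical(g), dim(g), off), dim(g)),
             mask$spacing_mm)
}

#' Morphological dilation with a ball structuring element
#' @inheritParams binary_opening
#' @return The dilated [voxel_mask()].
#' @export
binary_dilation <- function(mask, ball_radius_vox = 3.0) {
  stopifnot(inherits(mask, "voxel_mask"))
  off <- ball_offsets(ball_radius_vox)
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  g <- mask$grid
  voxel_mask(array(cpp_dilate(as.logical(g), dim(g), off), dim(g)),
             mask$spacing_mm)
}

#' Connected-component labeling
#'
#' Maximal connected components under 6- or 26-connectivity; labels are
#' assigned in raster order of each component's first voxel, so the result
#' is deterministic.
#'
#' @param mask A [voxel_mask()].
#' @param connectivity 26 (default, standard for pore labeling) or 6.
#' @return A [label_map()].
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "voxel_mask"))
  conn <- as.integer(connectivity)
  if (!conn %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  g <- mask$grid
  res <- cpp_label(as.logical(g), dim(g), conn)
  label_map(array(res$labels, dim(g)), res$n, mask$spacing_mm)
}
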