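# Shared fixtures: digitized solids, brute-force morphology oracles, and
# small phantom specs. Everything is built in code at test time.

# digitized sphere: voxel centers within r of the grid center (voxel units)
sphere_mask <- function(r, pad = 3, spacing = 1) {
  n <- 2 * ceiling(r) + 1 + 2 * pad
  c0 <- (n + 1) / 2
  x <- slice.index(array(0, c(n, n, n)), 1) - c0
  y <- slice.index(array(0, c(n, n, n)), 2) - c0
  z <- slice.index(array(0, c(n, n, n)), 3) - c0
  voxel_mask(x^2 + y^2 + z^2 <= r^2, spacing)
}

# axis-aligned solid cylinder along z
cylinder_mask <- function(r, len, pad = 3, spacing = 1) {
  n <- 2 * ceiling(r) + 1 + 2 * pad
  c0 <- (n + 1) / 2
  g <- array(FALSE, c(n, n, len))
  x <- slice.index(array(0, c(n, n)), 1) - c0
  y <- slice.index(array(0, c(n, n)), 2) - c0
  disk <- x^2 + y^2 <= r^2
  for (z in seq_len(len)) g[, , z] <- disk
  voxel_mask(g, spacing)
}

# definition-level erosion/dilation by shifting, the independent oracle for
# the C++ morphology (outside the grid counts as background)
shift_and <- function(g, off, combine) {
  d <- dim(g)
  out <- if (combine == "and") g else g
  for (k in seq_len(nrow(off))) {
    sh <- array(FALSE, d)
    src <- lapply(1:3, function(a) seq_len(d[a]) +
                    (if (combine == "and") off[k, a] else -off[k, a]))
    ii <- lapply(1:3, function(a) which(src[[a]] >= 1 & src[[a]] <= d[a]))
    sh[ii[[1]], ii[[2]], ii[[3]]] <-
      g[src[[1]][ii[[1]]], src[[2]][ii[[2]]], src[[3]][ii[[3]]]]
    out <- if (combine == "and") out & sh else out | sh
  }
  out
}
brute_opening <- function(g, radius) {
  off <- ball_offsets(radius)
  shift_and(shift_and(g, off, "and"), off, "or")
}

# histogram object from raw counts (integer bin edges of width bw from 0)
hist_from_counts <- function(counts, bw = 10L) {
  structure(list(bin_edges = as.integer(seq(0, bw * length(counts), bw)),
                 counts = as.integer(counts)),
            class = "gsv_histogram")
}

# small bun phantom (about 100^3) used across module tests
small_spec <- function(seed = 7, ...) {
  args <- list(body_semi_axes_mm = c(7, 7, 6), margin_mm = 0.8, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantom_spec, args)
}

quiet_config <- function(...) pipeline_config(verbose = FALSE, ...)
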