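test_that("distance transform matches brute-force nearest-background search", {
  brute <- function(g, spacing) {
    d <- dim(g)
    bg <- which(!g, arr.ind = TRUE)
    out <- array(0, d)
    fg <- which(g, arr.ind = TRUE)
    for (i in seq_len(nrow(fg))) {
      dd <- sweep(bg, 2, fg[i, ], "-")
      dd <- sweep(dd, 2, spacing, "*")
      out[fg[i, 1], fg[i, 2], fg[i, 3]] <- sqrt(min(rowSums(dd^2)))
    }
    out
  }
  # single voxel: distance one spacing
  g <- array(FALSE, c(5, 5, 5)); g[3, 3, 3] <- TRUE
  dm <- distance_transform(voxel_mask(g, 0.5))
  expect_equal(dm$values[3, 3, 3], 0.5)
  expect_true(all(dm$values[!g] == 0))
  # 9-voxel slab: mid-plane at 5 spacings
  g2 <- array(FALSE, c(7, 7, 11)); g2[, , 2:10] <- TRUE
  dm2 <- distance_transform(voxel_mask(g2, 1))
  expect_equal(dm2$values[4, 4, 6], 5)
  expect_equal(dm2$values, brute(g2, c(1, 1, 1)))
  # random mask, anisotropic spacing
  set.seed(3)
  g3 <- array(runif(9^3) < 0.6, c(9, 9, 9))
  sp <- c(0.16, 0.16, 0.25)
  dm3 <- distance_transform(voxel_mask(g3, sp))
  expect_equal(dm3$values, brute(g3, sp), tolerance = 1e-12)
  # cylinder axis distance about the radius
  cyl <- cylinder_mask(4, 20)
  dmc <- distance_transform(cyl)
  axis_d <- dmc$values[ceiling(dim(cyl$grid)[1] / 2),
                       ceiling(dim(cyl$grid)[2] / 2), 10]
  expect_lt(abs(axis_d - 4), 0.5)
})

test_that("skeletonization preserves topology and reduces cylinders to paths", {
  # single voxel is its own skeleton
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE
  expect_identical(skeletonize(voxel_mask(g))$grid, g)
  # solid cylinder r=4, length 40: one 26-connected path of about 40 voxels
  cyl <- cylinder_mask(4, 40)
  sk <- skeletonize(cyl)
  expect_true(all(cyl$grid[sk$grid]))                  # subset of the mask
  expect_equal(label_components(sk)$n_labels, 1)
  expect_lte(abs(sum(sk$grid) - 40), 4)
  # two disjoint blobs keep two components
  g2 <- array(FALSE, c(20, 9, 9))
  for (x in 1:20) for (y in 1:9) for (z in 1:9) {
    if ((x - 5)^2 + (y - 5)^2 + (z - 5)^2 <= 9) g2[x, y, z] <- TRUE
    if ((x - 15)^2 + (y - 5)^2 + (z - 5)^2 <= 9) g2[x, y, z] <- TRUE
  }
  sk2 <- skeletonize(voxel_mask(g2))
  expect_equal(label_components(sk2)$n_labels, 2)
})

test_that("skeleton component counts equal mask component counts on random masks", {
  set.seed(11)
  for (i in 1:8) {
    g <- array(runif(14^3) < 0.45, c(14, 14, 14))
    g <- binary_dilation(voxel_mask(g), 1)$grid        # coherent blobs
    m <- voxel_mask(g)
    expect_equal(label_components(skeletonize(m))$n_labels,
                 label_components(m)$n_labels)
  }
})

test_that("skeleton graphs have the expected node/segment structure", {
  # straight 10-voxel path: 2 endpoint nodes, 1 segment
  g <- array(FALSE, c(3, 3, 14)); g[2, 2, 3:12] <- TRUE
  m <- voxel_mask(g, 1)
  net <- skeleton_to_graph(m, distance_transform(m), prune_factor = 0)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$segments), 1)
  expect_equal(net$nodes$degree, c(1, 1))
  expect_equal(net$segments$length_mm, 9)
  expect_equal(net$n_components, 1)
  # Y shape: one junction of degree 3, three segments. The two branches
  # leave the junction diagonally so no parasitic 26-adjacency forms
  # between stem and branch voxels.
  gy <- array(FALSE, c(15, 15, 15))
  gy[8, 8, 2:8] <- TRUE                      # stem along z
  for (k in 1:5) gy[8 + k, 8, 8 + k] <- TRUE # branch 1 (x-z diagonal)
  for (k in 1:5) gy[8 - k, 8, 8 + k] <- TRUE # branch 2 (mirrored)
  my <- voxel_mask(gy, 1)
  nety <- skeleton_to_graph(my, distance_transform(my), prune_factor = 0)
  expect_equal(nrow(nety$segments), 3)
  expect_equal(sum(nety$nodes$degree == 3), 1)
  expect_equal(sum(nety$nodes$degree == 1), 3)
  # degree sum equals twice the segment incidences
  expect_equal(sum(nety$nodes$degree), 2 * nrow(nety$segments))
  # isolated cycle: one closed segment with a deterministic anchor; a
  # diamond of diagonal steps keeps every voxel at exactly two neighbors
  gc <- array(FALSE, c(8, 8, 3))
  ring <- cbind(c(4, 5, 6, 5, 4, 3, 2, 3), c(2, 3, 4, 5, 6, 5, 4, 3), 2)
  gc[ring] <- TRUE
  mc <- voxel_mask(gc, 1)
  netc <- skeleton_to_graph(mc, distance_transform(mc), prune_factor = 0)
  expect_equal(nrow(netc$segments), 1)
  expect_equal(netc$segments$node_a, netc$segments$node_b)
  # empty skeleton: empty network, all-zero summary
  empty <- voxel_mask(array(FALSE, c(3, 3, 3)))
  net0 <- skeleton_to_graph(empty, distance_transform(empty))
  expect_equal(nrow(net0$nodes), 0)
  su0 <- network_summary(net0)
  expect_true(all(su0 == 0))
})

test_that("cylinder throat radii are recovered within half a voxel", {
  for (r in c(3, 5, 8)) {
    cyl <- cylinder_mask(r, 30, spacing = 0.16)
    dm <- distance_transform(cyl)
    sk <- skeletonize(cyl)
    net <- skeleton_to_graph(sk, dm, prune_factor = 1)
    expect_equal(nrow(net$segments), 1)
    expect_lt(abs(net$segments$min_radius_mm - r * 0.16), 0.5 * 0.16)
  }
})

test_that("network summaries aggregate lengths and throats", {
  g <- array(FALSE, c(3, 3, 44)); g[2, 2, 3:42] <- TRUE  # 40-voxel path
  m <- voxel_mask(g, 0.16)
  net <- skeleton_to_graph(m, distance_transform(m), prune_factor = 0)
  su <- network_summary(net)
  expect_equal(su$total_length_mm, 39 * 0.16)
  expect_equal(su$n_segments, 1)
  expect_equal(su$mean_degree, 1)
})

test_that("storage makes pore throats wider (series trend)", {
  # needs a body large enough that throat statistics are not dominated by
  # a handful of branches
  base <- phantom_spec(body_semi_axes_mm = c(8, 8, 7), margin_mm = 0.8,
                       seed = 5)
  series <- generate_storage_series(base, seed = 5)
  cfg <- quiet_config()
  throat <- function(day) {
    an <- analyze_volume(series$days[[day]]$phantom$volume, cfg)
    an$network_summary$mean_throat_radius_mm
  }
  expect_gt(throat(5), throat(1))
})
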