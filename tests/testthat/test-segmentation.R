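test_that("histograms conserve voxel counts and place values correctly", {
  v <- voxel_volume(array(-500L, c(4, 4, 4)), volume_meta(c(4, 4, 4)))
  h <- compute_histogram(v, 50)
  expect_equal(sum(h$counts), 64)
  occ <- which(h$counts > 0)
  expect_length(occ, 1)
  expect_true(h$bin_edges[occ] <= -500 && h$bin_edges[occ + 1] > -500)

  vals <- array(rep(c(-1100L, -500L), each = 4), c(2, 2, 2))
  h2 <- compute_histogram(voxel_volume(vals, volume_meta(c(2, 2, 2))), 100)
  expect_equal(sort(h2$counts[h2$counts > 0]), c(4, 4))

  set.seed(1)
  v3 <- voxel_volume(array(sample(-2000:0, 5 * 6 * 7, TRUE), c(5, 6, 7)),
                     volume_meta(c(5, 6, 7)))
  expect_equal(sum(compute_histogram(v3, 7)$counts), 5 * 6 * 7)
  # region restriction conserves the region count
  reg <- voxel_mask(array(c(TRUE, FALSE), c(5, 6, 7)))
  expect_equal(sum(compute_histogram(v3, 10, reg)$counts), sum(reg$grid))
  expect_error(compute_histogram(v3, 10, voxel_mask(array(FALSE, c(5, 6, 7)))),
               "empty region")
})

test_that("balanced histogram threshold splits symmetric and skewed histograms", {
  # symmetric bimodal: middle bin's lower edge
  expect_equal(balanced_histogram_threshold(hist_from_counts(c(5, 0, 0, 0, 5))), 20)
  expect_equal(balanced_histogram_threshold(
    hist_from_counts(c(1, 2, 3, 4, 10, 4, 3, 2, 1))), 40)
  expect_error(balanced_histogram_threshold(hist_from_counts(c(0, 0, 0))),
               "all-zero")
})

test_that("balanced histogram threshold matches a step-by-step balance loop", {
  # independent oracle: literal simulation of the removal loop
  oracle <- function(counts, edges) {
    h <- as.numeric(counts)
    nz <- which(h > 0)
    l <- nz[1]; r <- nz[length(nz)]
    while (r > l) {
      ctr <- (l + r) / 2
      wl <- 0; wr <- 0
      for (i in l:r) {
        if (i < ctr) wl <- wl + h[i]
        else if (i > ctr) wr <- wr + h[i]
        else { wl <- wl + h[i] / 2; wr <- wr + h[i] / 2 }
      }
      if (wl > wr) l <- l + 1
      else if (wr > wl) r <- r - 1
      else if (r - l >= 2) { l <- l + 1; r <- r - 1 }
      else r <- r - 1
    }
    edges[l]
  }
  h <- hist_from_counts(c(9, 1, 0, 0, 2))
  expect_equal(oracle(h$counts, h$bin_edges), 20)   # hand-traced value
  expect_equal(balanced_histogram_threshold(h), 20)
  set.seed(42)
  for (i in 1:25) {
    counts <- rpois(sample(3:12, 1), 3)
    if (sum(counts) == 0) counts[1] <- 1
    hh <- hist_from_counts(counts)
    expect_equal(balanced_histogram_threshold(hh),
                 oracle(hh$counts, hh$bin_edges))
  }
})

test_that("band thresholding uses a closed interval", {
  v <- voxel_volume(array(c(-800L, -500L, -100L, -750L, -250L, 0L), c(6, 1, 1)),
                    volume_meta(c(6, 1, 1)))
  m <- band_threshold(v, -750, -250)
  expect_identical(as.vector(m$grid), c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_true(all(band_threshold(v, -32768, 32767)$grid))
  expect_error(band_threshold(v, -250, -750), "lo")
})

test_that("the pore band separates phantom phases almost perfectly", {
  ph <- generate_bun_phantom(small_spec(seed = 9))
  pores_true <- ph$truth$phase == 2L
  m <- band_threshold(ph$volume, -1250, -1000)
  expect_gte(sum(m$grid & pores_true) / sum(pores_true), 0.99)
  matrix_true <- ph$truth$phase == 1L
  expect_lte(sum(m$grid & matrix_true) / sum(matrix_true), 0.005)
})

test_that("fill_holes fills enclosed cavities, keeps vented ones, is monotone", {
  g <- array(FALSE, c(5, 5, 5)); g[1:5, 1:5, 1:5] <- TRUE
  g[2:4, 2:4, 2:4] <- FALSE
  f <- fill_holes(voxel_mask(g))
  expect_true(all(f$grid))
  # a 1-voxel channel from cavity to a face vents it
  g2 <- g; g2[3, 3, 1:2] <- FALSE
  expect_identical(fill_holes(voxel_mask(g2))$grid, g2)
  # all-false in, all-false out; idempotent; result superset of input
  empty <- voxel_mask(array(FALSE, c(4, 4, 4)))
  expect_false(any(fill_holes(empty)$grid))
  expect_identical(fill_holes(f)$grid, f$grid)
  expect_true(all(f$grid[g]))
})

test_that("mask_difference recovers the pore phase and clips violations", {
  g <- array(TRUE, c(3, 3, 3))
  m <- g; m[2, 2, 2] <- FALSE
  d <- mask_difference(voxel_mask(g), voxel_mask(m))
  expect_equal(sum(d$grid), 1)
  expect_true(d$grid[2, 2, 2])
  expect_false(any(mask_difference(voxel_mask(g), voxel_mask(g))$grid))
  # matrix voxel outside filled: reported and clipped
  g2 <- g; g2[1, 1, 1] <- FALSE
  expect_message(mask_difference(voxel_mask(g2), voxel_mask(g)), "clipped")
  expect_error(mask_difference(voxel_mask(g), voxel_mask(array(TRUE, c(2, 2, 2)))),
               "shapes")
})

test_that("opening equals the brute-force definition and removes thin structure", {
  # digitized sphere r=6 opened with r=3 equals definition-level result
  s6 <- sphere_mask(6, pad = 4)
  op <- binary_opening(s6, 3)
  expect_identical(op$grid, brute_opening(s6$grid, 3))
  # a 1-voxel rod vanishes
  rod <- array(FALSE, c(9, 9, 12)); rod[5, 5, 2:11] <- TRUE
  expect_false(any(binary_opening(voxel_mask(rod), 3)$grid))
  # dumbbell: two r=5 spheres joined by a thin neck -> 2 components
  g <- array(FALSE, c(13, 13, 30))
  for (co in c(8, 22)) {
    for (z in 1:30) for (x in 1:13) for (y in 1:13)
      if ((x - 7)^2 + (y - 7)^2 + (z - co)^2 <= 25) g[x, y, z] <- TRUE
  }
  g[7, 7, 8:22] <- TRUE
  opened <- binary_opening(voxel_mask(g), 3)
  expect_identical(opened$grid, brute_opening(g, 3))
  expect_equal(label_components(opened)$n_labels, 2)
})

test_that("opening is anti-extensive and idempotent", {
  set.seed(7)
  g <- array(runif(18^3) < 0.55, c(18, 18, 18))
  m <- voxel_mask(g)
  op1 <- binary_opening(m, 2)
  expect_true(all(g[op1$grid]))                     # subset of input
  expect_identical(binary_opening(op1, 2)$grid, op1$grid)
})

test_that("labeling respects connectivity and is deterministic raster order", {
  g <- array(FALSE, c(4, 4, 4)); g[1, 1, 1] <- TRUE; g[4, 4, 4] <- TRUE
  expect_equal(label_components(voxel_mask(g))$n_labels, 2)
  # corner-sharing voxels: one 26-component, two 6-components
  g2 <- array(FALSE, c(3, 3, 3)); g2[1, 1, 1] <- TRUE; g2[2, 2, 2] <- TRUE
  expect_equal(label_components(voxel_mask(g2), 26)$n_labels, 1)
  expect_equal(label_components(voxel_mask(g2), 6)$n_labels, 2)
  # labels are 1..n and partition the mask
  set.seed(8)
  g3 <- array(runif(15^3) < 0.3, c(15, 15, 15))
  lm <- label_components(voxel_mask(g3))
  expect_setequal(unique(as.vector(lm$grid[g3])), seq_len(lm$n_labels))
  expect_true(all(lm$grid[!g3] == 0L))
  # raster-order label assignment: first voxel of label 1 precedes label 2
  firsts <- vapply(seq_len(lm$n_labels), function(l) min(which(lm$grid == l)), 1L)
  expect_true(all(diff(firsts) > 0))
})

test_that("well-separated phantom spheres yield exactly k labels", {
  sp <- phantom_spec(body_semi_axes_mm = c(8, 8, 8), pore_count = 12,
                     target_porosity_pct = NULL, pore_radius_median_mm = 0.4,
                     pore_radius_log_sd = 0, margin_mm = 0.5, seed = 13)
  ph <- generate_bun_phantom(sp)
  sph <- ph$truth$pore_spheres
  dd <- as.matrix(dist(sph[, 1:3]))
  gaps <- dd - outer(sph$r_mm, sph$r_mm, "+")
  sep <- all(gaps[upper.tri(gaps)] > 2 * 0.16)   # pairwise gaps > 1 voxel
  skip_if_not(sep, "random draw placed overlapping spheres")
  lab <- label_components(voxel_mask(ph$truth$phase == 2L, 0.16))
  expect_equal(lab$n_labels, nrow(sph))
})
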