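test_that("a single voxel has closed-form volume and corner-based Feret", {
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE
  lab <- label_components(voxel_mask(g, 0.16))
  st <- measure_labels(lab)
  expect_equal(st$volume_mm3, 0.16^3)
  expect_equal(st$eq_diameter_mm, (6 * 0.16^3 / pi)^(1 / 3))
  # Feret of the unit cube over the direction set, scaled by spacing
  dirs <- feret_directions()
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 0.16
  ext <- apply(corners %*% dirs, 2, function(p) max(p) - min(p))
  expect_equal(st$length_mm, max(ext))
  expect_equal(st$width_mm, min(ext))
  expect_equal(unlist(st[, c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")],
                      use.names = FALSE), rep(1.5 * 0.16, 3))
})

test_that("digitized spheres recover analytic volume, area and diameter", {
  for (r in c(5, 8)) {
    st <- measure_labels(label_components(sphere_mask(r)))
    expect_lt(abs(st$volume_mm3 / (4 / 3 * pi * r^3) - 1), 0.05)
    expect_lt(abs(st$area_mm2 / (4 * pi * r^2) - 1), 0.05)
    expect_lt(abs(st$eq_diameter_mm / (2 * r) - 1), 0.03)
    expect_lt(abs(st$length_mm - 2 * r), sqrt(3))
    expect_lt(abs(st$width_mm - 2 * r), sqrt(3))
    expect_lte(st$width_mm, st$length_mm)
  }
  # physical spacing scales the measurements
  st <- measure_labels(label_components(sphere_mask(8, spacing = 0.16)))
  expect_lt(abs(st$volume_mm3 / (4 / 3 * pi * 1.28^3) - 1), 0.05)
  expect_lt(abs(st$area_mm2 / (4 * pi * 1.28^2) - 1), 0.05)
})

test_that("a 1x1x5 rod matches the exhaustive Feret oracle on its corners", {
  g <- array(FALSE, c(5, 5, 9)); g[3, 3, 3:7] <- TRUE
  lab <- label_components(voxel_mask(g, 0.16))
  st <- measure_labels(lab)
  # oracle: all 8*5 corner points, exhaustive projection over the same set
  corners <- do.call(rbind, lapply(3:7, function(z)
    as.matrix(expand.grid(2:3, 2:3, c(z - 1, z)))))
  corners <- corners * 0.16
  dirs <- feret_directions()
  ext <- apply(corners %*% dirs, 2, function(p) max(p) - min(p))
  expect_equal(st$length_mm, max(ext))
  expect_equal(st$width_mm, min(ext))
  expect_gte(st$length_mm, 5 * 0.16 - 1e-9)  # at least the axial extent
  expect_gte(st$width_mm, 0.16 - 1e-9)       # at least one voxel
  expect_lte(st$width_mm, 0.16 * sqrt(2) + 1e-9)
})

test_that("Feret width never exceeds length and survives axis rotations", {
  set.seed(5)
  g <- array(runif(12^3) < 0.4, c(12, 12, 12))
  g <- binary_opening(voxel_mask(g), 1.5)$grid    # some coherent blobs
  lab <- label_components(voxel_mask(g))
  st <- measure_labels(lab)
  expect_true(all(st$width_mm <= st$length_mm + 1e-12))
  # 90-degree rotation about z: x -> y, y -> -x
  gr <- aperm(g, c(2, 1, 3))[dim(g)[2]:1, , , drop = FALSE]
  str <- measure_labels(label_components(voxel_mask(gr)))
  expect_equal(sort(st$volume_mm3), sort(str$volume_mm3))
  expect_equal(sort(st$length_mm), sort(str$length_mm), tolerance = 0.02)
  expect_equal(sort(st$width_mm), sort(str$width_mm), tolerance = 0.02)
})

test_that("porosity is the voxel-count ratio with clipping and guards", {
  sample_g <- array(FALSE, c(10, 10, 10)); sample_g[1:10, 1:10, 1:10] <- TRUE
  pores_g <- array(FALSE, c(10, 10, 10)); pores_g[1:5, 1:5, 1:10] <- TRUE
  expect_equal(porosity(voxel_mask(pores_g), voxel_mask(sample_g)), 25)
  expect_equal(porosity(voxel_mask(array(FALSE, c(10, 10, 10))),
                        voxel_mask(sample_g)), 0)
  expect_error(porosity(voxel_mask(pores_g),
                        voxel_mask(array(FALSE, c(10, 10, 10)))), "empty sample")
  # porosity is scale-free under spacing changes
  expect_equal(porosity(voxel_mask(pores_g, 0.5), voxel_mask(sample_g, 0.5)), 25)
})

test_that("summaries average pore stats and convert units", {
  st <- data.frame(label = 1:2, volume_mm3 = c(5, 10), area_mm2 = c(10, 20),
                   eq_diameter_mm = c(1, 2), length_mm = c(2, 3),
                   width_mm = c(1, 2), centroid_x_mm = 0, centroid_y_mm = 0,
                   centroid_z_mm = 0, touches_border = c(FALSE, TRUE))
  g <- array(TRUE, c(100, 100, 100))
  pores <- array(FALSE, c(100, 100, 100)); pores[1:10, 1:10, 1:10] <- TRUE
  su <- summarize_morphometry(st, voxel_mask(pores, 0.16), voxel_mask(g, 0.16))
  expect_equal(su$mean_volume_mm3, 7.5)
  expect_equal(su$mean_area_mm2, 15)
  expect_equal(su$pore_count, 2)
  expect_equal(su$sample_volume_mL, 1e6 * 0.16^3 / 1000)  # 4.096 mL
  expect_equal(su$porosity_pct, 0.1)
  # border filter drops the flagged pore
  su2 <- summarize_morphometry(st, voxel_mask(pores, 0.16),
                               voxel_mask(g, 0.16), drop_border_pores = TRUE)
  expect_equal(su2$pore_count, 1)
  expect_equal(su2$mean_volume_mm3, 5)
  # zero pores: NA means, porosity 0
  su0 <- summarize_morphometry(st[0, ], voxel_mask(array(FALSE, c(4, 4, 4))),
                               voxel_mask(array(TRUE, c(4, 4, 4))))
  expect_true(is.na(su0$mean_volume_mm3))
  expect_equal(su0$porosity_pct, 0)
})

test_that("size distribution bins are half-open with a reported overflow", {
  st <- data.frame(eq_diameter_mm = c(1.5, 3.0, 7.0))
  sd1 <- size_distribution(st)
  expect_equal(sd1$count, c(1, 1, 0, 1, 0, 0))
  expect_equal(sd1$percentage, c(100 / 3, 100 / 3, 0, 100 / 3, 0, 0))
  expect_equal(sum(sd1$percentage), 100)
  # edge membership: a value at an edge belongs to the upper bin
  expect_equal(size_distribution(data.frame(eq_diameter_mm = 2))$count[2], 1)
  # overflow collected and counted
  sd2 <- size_distribution(data.frame(eq_diameter_mm = c(1, 12)))
  expect_equal(sd2$count[nrow(sd2)], 1)
  expect_equal(sum(sd2$count), 2)
  expect_true(all(size_distribution(st[0, , drop = FALSE])$count == 0))
})

test_that("phantom pores drawn below 2 mm diameter all land in the first bin", {
  sp <- phantom_spec(body_semi_axes_mm = c(7, 7, 6), pore_count = 25,
                     target_porosity_pct = NULL, pore_radius_median_mm = 0.5,
                     pore_radius_log_sd = 0.1, margin_mm = 0.6, seed = 17)
  ph <- generate_bun_phantom(sp)
  expect_true(all(2 * ph$truth$pore_spheres$r_mm < 2))
  lab <- label_components(voxel_mask(ph$truth$phase == 2L, 0.16))
  st <- measure_labels(lab)
  sdist <- size_distribution(st)
  # merged pores may exceed a single sphere, but allow one bin of tolerance
  # only for diameters within 5% of the edge
  expect_true(all(st$eq_diameter_mm < 2 * 1.05))
  expect_gte(sdist$percentage[1], 90)
})

test_that("cubic ROIs extract faithfully and local pore fraction counts the band", {
  ph <- generate_bun_phantom(small_spec(seed = 19))
  shp <- dim(ph$volume$values)
  ctr <- shp %/% 2
  cube <- extract_cube_roi(ph$volume, ctr, 45)
  expect_equal(dim(cube$values), c(45, 45, 45))
  expect_error(extract_cube_roi(ph$volume, c(2, 2, 2), 45), "axis")
  expect_equal(dim(extract_cube_roi(ph$volume, ctr, 1)$values), c(1, 1, 1))
  # overlapping cubes agree on their intersection
  c1 <- extract_cube_roi(ph$volume, ctr, 21)
  c2 <- extract_cube_roi(ph$volume, ctr + c(4L, 0L, 0L), 21)
  expect_identical(c1$values[5:21, , ], c2$values[1:17, , ])
  # pure-phase cubes give 0 and 100
  mat_cube <- voxel_volume(array(-500L, c(5, 5, 5)), volume_meta(c(5, 5, 5)))
  expect_equal(local_pore_fraction(mat_cube), 0)
  pore_cube <- voxel_volume(array(-1100L, c(5, 5, 5)), volume_meta(c(5, 5, 5)))
  expect_equal(local_pore_fraction(pore_cube), 100)
  # fraction tracks the ground-truth phase fraction in the cube
  # (cube spans 0-based [ctr - 22, ctr + 23), i.e. R indices ctr-21..ctr+23)
  truth_frac <- 100 * mean(ph$truth$phase[
    (ctr[1] - 21):(ctr[1] + 23), (ctr[2] - 21):(ctr[2] + 23),
    (ctr[3] - 21):(ctr[3] + 23)] == 2L)
  expect_lt(abs(local_pore_fraction(cube) - truth_frac), 1.5)
})

test_that("a denser center shows a lower local pore fraction than the skin", {
  # radially weighted pore placement emulates the tighter, moisture-rich
  # center of real crumb: a cube at the body center must read a lower
  # pore fraction than one at mid-radius toward the skin
  sp <- small_spec(seed = 23, pore_radial_power = 2)
  ph <- generate_bun_phantom(sp)
  shp <- dim(ph$volume$values)
  ctr <- shp %/% 2
  off <- c(ctr[1] + round(0.55 * 7 / 0.16), ctr[2], ctr[3])  # toward skin
  center_cube <- extract_cube_roi(ph$volume, ctr, 31)
  skin_cube <- extract_cube_roi(ph$volume, off, 31)
  truth_at <- function(c0, side) {
    h <- side %/% 2
    100 * mean(ph$truth$phase[(c0[1] - h + 1):(c0[1] + h + 1),
                              (c0[2] - h + 1):(c0[2] + h + 1),
                              (c0[3] - h + 1):(c0[3] + h + 1)] == 2L)
  }
  expect_gt(truth_at(off, 31), truth_at(ctr, 31))
  expect_gt(local_pore_fraction(skin_cube), local_pore_fraction(center_cube))
})
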