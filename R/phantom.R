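# Seeded CT phantoms of a porous bun, and a 5-day storage series with
# physicochemical covariates, carrying exact voxel-level ground truth.
#
# The phantom emulates the study conditions of a bench-top bread-crumb
# scan: an ellipsoidal solid matrix whose grayscale values concentrate in
# the -750..-250 band, pore and exterior air drawn from a band around
# -1100 (captured by the -1250..-1000 local band), 160 um voxels, and a
# storage series whose porosity grows while the body shrinks. Exterior air
# deliberately shares the pore grayscale distribution - physically both are
# air - so recovering interior pores requires the full fill-holes +
# subtraction chain, not just a threshold.

#' Phantom specification
#'
#' Geometry, pore population and grayscale model of a synthetic bun. The
#' defaults reproduce the study conditions of a day-1 bread-crumb scan: a
#' 165 mL ellipsoidal body at 0.16 mm voxels, matrix GSVs at -500 +- 80
#' (>= 99.7% inside the -750..-250 band) and pore/air GSVs at -1100 +- 40
#' (>= 99% inside the -1250..-1000 pore band).
#'
#' @param body_semi_axes_mm Ellipsoid semi-axes (mm). The default
#'   `c(42, 42, 22.3)` gives a 164.6 mL body, matching a fresh sample.
#' @param pore_count Number of pores to place, or `NULL` to fill until
#'   `target_porosity_pct` is reached.
#' @param target_porosity_pct Pore-phase fraction of the body to aim for;
#'   pores are added until the phase-grid porosity reaches it. Default 23.5.
#' @param pore_radius_median_mm,pore_radius_log_sd Log-normal pore radius
#'   parameters. Defaults (0.55 mm median, log-sd 0.35) put nearly all
#'   equivalent diameters in the 0-4 mm bins of a fresh crumb.
#' @param matrix_gsv,pore_gsv Mean/sd pairs of the per-phase Gaussian GSV
#'   draws; the bands must not overlap at +-3 sd. `pore_gsv` is also used
#'   for exterior air. Draws are clipped to \[-32768, 32767\].
#' @param delamination Optional `list(z_mm =, thickness_mm =)` planar air
#'   gap (normal to z, position measured from the volume origin), clipped
#'   to the body. Emulates the skin-crumb separation of aged samples.
#' @param spacing_mm Voxel spacing, default 0.160.
#' @param margin_mm Air margin around the body, default 1 mm.
#' @param skin_mm Pore-free shell thickness under the body surface, default
#'   0.4 mm. Bread develops a denser closed skin during steaming; the shell
#'   also keeps interior pores enclosed so the fill-holes chain can recover
#'   them.
#' @param pore_radial_power Radial weighting of pore placement: centers are
#'   accepted with probability `u^power`, where `u` in \[0, 1\] is the
#'   ellipsoidal radius. 0 (default) places pores uniformly; positive values
#'   concentrate pores toward the periphery, emulating the tighter,
#'   moisture-rich center of real crumb.
#' @param seed Integer seed; all randomness derives from it.
#' @param max_place_tries Rejection-sampling budget per pore.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_semi_axes_mm = c(42, 42, 22.3),
                         pore_count = NULL,
                         target_porosity_pct = 23.5,
                         pore_radius_median_mm = 0.55,
                         pore_radius_log_sd = 0.35,
                         matrix_gsv = c(mean = -500, sd = 80),
                         pore_gsv = c(mean = -1100, sd = 40),
                         delamination = NULL,
                         spacing_mm = 0.160,
                         margin_mm = 1.0,
                         skin_mm = 0.4,
                         pore_radial_power = 0,
                         seed = 1L,
                         max_place_tries = 200L) {
  if (length(body_semi_axes_mm) != 3L || any(body_semi_axes_mm <= 0))
    stop("'body_semi_axes_mm' must be three positive reals")
  if (!is.null(pore_count) && pore_count < 0) stop("'pore_count' must be >= 0")
  if (is.null(pore_count) && is.null(target_porosity_pct))
    stop("give either 'pore_count' or 'target_porosity_pct'")
  if (pore_radius_median_mm <= 0) stop("pore radius median must be > 0")
  if (matrix_gsv[1] - 3 * matrix_gsv[2] <= pore_gsv[1] + 3 * pore_gsv[2])
    stop("matrix and pore GSV bands overlap at +-3 sd; phases would not separate")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (!is.null(delamination) &&
      (is.null(delamination$z_mm) || is.null(delamination$thickness_mm)))
    stop("'delamination' needs z_mm and thickness_mm")
  structure(list(body_semi_axes_mm = as.numeric(body_semi_axes_mm),
                 pore_count = pore_count,
                 target_porosity_pct = target_porosity_pct,
                 pore_radius_median_mm = pore_radius_median_mm,
                 pore_radius_log_sd = pore_radius_log_sd,
                 matrix_gsv = unname(matrix_gsv), pore_gsv = unname(pore_gsv),
                 delamination = delamination,
                 spacing_mm = as.numeric(spacing_mm),
                 margin_mm = margin_mm, skin_mm = skin_mm,
                 pore_radial_power = pore_radial_power,
                 seed = as.integer(seed),
                 max_place_tries = as.integer(max_place_tries)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  vol_mL <- 4 / 3 * pi * prod(x$body_semi_axes_mm) / 1000
  tgt <- if (is.null(x$pore_count))
    sprintf("target porosity %.1f%%", x$target_porosity_pct)
  else sprintf("%d pores", x$pore_count)
  cat(sprintf("Bun phantom spec: semi-axes %s mm (%.1f mL), %s, seed %d\n",
              paste(format(x$body_semi_axes_mm), collapse = " x "),
              vol_mL, tgt, x$seed))
  invisible(x)
}

phantom_grid_shape <- function(spec) {
  ext <- 2 * spec$body_semi_axes_mm + 2 * spec$margin_mm
  as.integer(ceiling(ext / spec$spacing_mm))
}

# voxel-center coordinates (mm) along one axis, 0-based convention
axis_centers <- function(n, s) (seq_len(n) - 0.5) * s

#' Generate a bun phantom with ground truth
#'
#' Places spherical pores with centers uniform inside the body,
#' rejection-sampled so each sphere lies fully inside (overlaps between
#' pores are allowed; small pores merging into larger ones is part of what
#' the phantom emulates). Voxel phase is pore if the voxel center falls
#' inside any sphere or the delamination slab, matrix if inside the
#' ellipsoid otherwise, and exterior elsewhere. GSVs are drawn per phase.
#' Output is deterministic for a fixed spec and seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `bun_phantom`: `volume` (a [voxel_volume()]) and
#'   `truth` (class `phantom_truth`) holding `pore_spheres` (center mm,
#'   radius mm), `phase` (3D array: 0 exterior, 1 matrix, 2 pore),
#'   `true_porosity_pct` (pore voxels inside the body / body voxels x 100,
#'   exact by construction) and `true_body_volume_mL`.
#' @export
generate_bun_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  s <- spec$spacing_mm
  shp <- phantom_grid_shape(spec)
  ax <- spec$body_semi_axes_mm
  ctr <- shp * s / 2
  ex <- ((axis_centers(shp[1], s[1]) - ctr[1]) / ax[1])^2
  ey <- ((axis_centers(shp[2], s[2]) - ctr[2]) / ax[2])^2
  ez <- ((axis_centers(shp[3], s[3]) - ctr[3]) / ax[3])^2
  body <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  n_body <- sum(body)
  if (n_body == 0L) stop("degenerate spec: body contains no voxels")

  pore <- array(FALSE, dim = shp)
  n_pore_in_body <- 0L                  # running count, updated per sphere
  spheres <- list()
  place_sphere <- function(r) {
    # accept centers inside the ellipsoid shrunk by r plus the skin on
    # every semi-axis; every such sphere lies fully inside the body with a
    # pore-free shell above it
    sh <- ax - r - spec$skin_mm
    if (any(sh <= 0)) return(NULL)
    p <- spec$pore_radial_power
    for (t in seq_len(spec$max_place_tries)) {
      c_mm <- runif(3, -ax, ax)
      u2 <- sum((c_mm / sh)^2)
      if (u2 > 1) next
      if (p > 0 && runif(1) > sqrt(u2)^p) next
      return(c_mm + ctr)
    }
    NULL
  }
  paint_sphere <- function(c_mm, r) {
    lo <- pmax(1L, as.integer(floor((c_mm - r) / s - 0.5) + 1L))
    hi <- pmin(shp, as.integer(ceiling((c_mm + r) / s + 0.5)))
    xs <- axis_centers(shp[1], s[1])[lo[1]:hi[1]] - c_mm[1]
    ys <- axis_centers(shp[2], s[2])[lo[2]:hi[2]] - c_mm[2]
    zs <- axis_centers(shp[3], s[3])[lo[3]:hi[3]] - c_mm[3]
    inside <- outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= r^2
    blk <- pore[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    new <- inside & !blk
    body_blk <- body[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    n_pore_in_body <<- n_pore_in_body + sum(new & body_blk)
    pore[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <<- blk | inside
  }

  n_target <- spec$pore_count
  repeat {
    if (!is.null(n_target)) {
      if (length(spheres) >= n_target) break
    } else {
      if (100 * n_pore_in_body / n_body >= spec$target_porosity_pct) break
    }
    r <- rlnorm(1, meanlog = log(spec$pore_radius_median_mm),
                sdlog = spec$pore_radius_log_sd)
    c_mm <- place_sphere(r)
    if (is.null(c_mm)) {
      if (!is.null(n_target))
        stop(sprintf("could not place pore %d of %d within %d tries (achieved %d)",
                     length(spheres) + 1L, n_target, spec$max_place_tries,
                     length(spheres)))
      next   # radius too large for the body; redraw
    }
    spheres[[length(spheres) + 1L]] <- c(c_mm, r)
    paint_sphere(c_mm, r)
  }

  if (!is.null(spec$delamination)) {
    zc <- axis_centers(shp[3], s[3])
    slab <- abs(zc - spec$delamination$z_mm) <= spec$delamination$thickness_mm / 2
    if (any(slab)) {
      shk <- pmax(ax - spec$skin_mm, 0.1)
      core <- outer(outer(((axis_centers(shp[1], s[1]) - ctr[1]) / shk[1])^2,
                          ((axis_centers(shp[2], s[2]) - ctr[2]) / shk[2])^2,
                          "+"),
                    ((axis_centers(shp[3], s[3]) - ctr[3]) / shk[3])^2,
                    "+") <= 1
      slab3 <- array(rep(slab, each = shp[1] * shp[2]), dim = shp)
      pore <- pore | (slab3 & core)     # clipped under the skin
    }
  }
  pore <- pore & body                   # voxel-level interior guarantee

  phase <- array(0L, dim = shp)
  phase[body] <- 1L
  phase[pore] <- 2L

  n_pore <- sum(pore)
  gsv <- array(0L, dim = shp)
  n_air <- length(gsv) - n_body + n_pore
  draw <- function(n, p) as.integer(pmin(32767, pmax(-32768, round(rnorm(n, p[1], p[2])))))
  gsv[phase != 1L] <- draw(n_air, spec$pore_gsv)
  gsv[phase == 1L] <- draw(n_body - n_pore, spec$matrix_gsv)

  sph <- if (length(spheres)) {
    m <- do.call(rbind, spheres)
    data.frame(cx_mm = m[, 1], cy_mm = m[, 2], cz_mm = m[, 3], r_mm = m[, 4])
  } else {
    data.frame(cx_mm = numeric(0), cy_mm = numeric(0), cz_mm = numeric(0),
               r_mm = numeric(0))
  }
  truth <- structure(list(
    pore_spheres = sph,
    phase = phase,
    true_porosity_pct = 100 * n_pore / n_body,
    true_body_volume_mL = n_body * prod(s) / 1000), class = "phantom_truth")
  structure(list(volume = voxel_volume(gsv, volume_meta(shp, s)),
                 truth = truth, spec = spec),
            class = "bun_phantom")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("Phantom ground truth: %d pores, porosity %.2f%%, body %.2f mL\n",
              nrow(x$pore_spheres), x$true_porosity_pct, x$true_body_volume_mL))
  invisible(x)
}

#' @export
print.bun_phantom <- function(x, ...) {
  print(x$volume); print(x$truth)
  invisible(x)
}

#' Storage-series trend parameters
#'
#' Per-day endpoints are interpolated linearly over the storage days. The
#' defaults are the observed study conditions for steamed bread aging over
#' 5 days at room temperature: porosity 23.5 -> 28.8%, sample volume
#' 165.33 -> 126.37 mL (applied to phantoms as a relative shrinkage),
#' hardness 10.1 -> 40.4 N, flexibility 6.5 -> 6.0 mm, and region-wise
#' moisture curves ordered center > crumb > skin throughout. Hardness is
#' generated as an affine function of center moisture plus Gaussian noise;
#' with `hardness_noise_sd = 0` it is exactly affine in moisture.
#'
#' @param porosity_pct,body_volume_mL,hardness_N,flexibility_mm Numeric
#'   `c(start, end)` pairs.
#' @param moisture_center,moisture_crumb,moisture_skin Moisture (%)
#'   `c(start, end)` pairs per region.
#' @param pore_radius_scale Relative growth of the median pore radius,
#'   `c(start, end)`; pores coarsen as small ones merge into larger ones
#'   during aging (mean pore volume roughly doubles over 5 days).
#' @param hardness_noise_sd Gaussian sd of the hardness noise (N).
#' @param moisture_noise_sd Gaussian sd added to each region's moisture (%).
#' @return An object of class `storage_trend`.
#' @export
storage_trend <- function(porosity_pct = c(23.5, 28.8),
                          body_volume_mL = c(165.33, 126.37),
                          hardness_N = c(10.1, 40.4),
                          flexibility_mm = c(6.5, 6.0),
                          moisture_center = c(42, 38),
                          moisture_crumb = c(40, 34),
                          moisture_skin = c(36, 26),
                          pore_radius_scale = c(1, 1.3),
                          hardness_noise_sd = 1.5,
                          moisture_noise_sd = 0) {
  tr <- structure(list(porosity_pct = porosity_pct,
                       body_volume_mL = body_volume_mL,
                       hardness_N = hardness_N,
                       flexibility_mm = flexibility_mm,
                       moisture_center = moisture_center,
                       moisture_crumb = moisture_crumb,
                       moisture_skin = moisture_skin,
                       pore_radius_scale = pore_radius_scale,
                       hardness_noise_sd = hardness_noise_sd,
                       moisture_noise_sd = moisture_noise_sd),
                  class = "storage_trend")
  if (diff(porosity_pct) < 0 || diff(body_volume_mL) > 0)
    warning("non-monotone trend endpoints (porosity should rise, volume shrink); simulating as given")
  tr
}

trend_interp <- function(endpoints, days) {
  if (days == 1L) return(endpoints[1])
  endpoints[1] + (endpoints[2] - endpoints[1]) * (seq_len(days) - 1) / (days - 1)
}

# hardness = a - b * moisture_center, mapped from the trend endpoints
hardness_coefs <- function(trend, days) {
  m <- trend_interp(trend$moisture_center, days)
  h <- trend_interp(trend$hardness_N, days)
  b <- -(h[days] - h[1]) / (m[days] - m[1])
  a <- h[1] + b * m[1]
  c(a = a, b = b)
}

#' Simulate storage-series covariates (no voxel data)
#'
#' Generates the per-day covariate table of a storage series: region-wise
#' moisture, hardness (affine in center moisture plus noise), flexibility,
#' and the trend porosity with optional Gaussian noise. Useful for
#' statistics validation at scale without generating voxel phantoms.
#'
#' @param days Number of storage days, default 5.
#' @param trend A [storage_trend()].
#' @param porosity_noise_sd Gaussian sd added to the trend porosity.
#' @param seed Integer seed.
#' @return A data.frame with one row per day: `day`, `hardness_N`,
#'   `flexibility_mm`, `moisture_center`, `moisture_crumb`, `moisture_skin`,
#'   `porosity_pct`.
#' @export
simulate_storage_covariates <- function(days = 5L, trend = storage_trend(),
                                        porosity_noise_sd = 0, seed = 1L) {
  set.seed(seed)
  days <- as.integer(days)
  mc <- trend_interp(trend$moisture_center, days) +
    rnorm(days, 0, trend$moisture_noise_sd)
  mb <- trend_interp(trend$moisture_crumb, days) +
    rnorm(days, 0, trend$moisture_noise_sd)
  ms <- trend_interp(trend$moisture_skin, days) +
    rnorm(days, 0, trend$moisture_noise_sd)
  ab <- hardness_coefs(trend, days)
  hard <- ab["a"] - ab["b"] * mc + rnorm(days, 0, trend$hardness_noise_sd)
  flex <- trend_interp(trend$flexibility_mm, days)
  por <- trend_interp(trend$porosity_pct, days) +
    rnorm(days, 0, porosity_noise_sd)
  data.frame(day = seq_len(days), hardness_N = hard, flexibility_mm = flex,
             moisture_center = mc, moisture_crumb = mb, moisture_skin = ms,
             porosity_pct = por)
}

#' Porosity noise level for a target population R-squared
#'
#' For a noiseless moisture trajectory, the trend porosity is exactly
#' affine in center moisture; adding Gaussian noise of the returned sd
#' makes the population coefficient of determination of the
#' porosity-on-moisture regression equal `r2`, using the sample variance of
#' the day-wise trend porosity as the signal variance.
#'
#' @param r2 Target population R-squared in (0, 1\].
#' @param trend A [storage_trend()].
#' @param days Number of storage days.
#' @return The Gaussian noise sd (porosity percentage points).
#' @export
porosity_noise_sd_for_r2 <- function(r2, trend = storage_trend(), days = 5L) {
  if (r2 <= 0 || r2 > 1) stop("'r2' must be in (0, 1]")
  signal <- trend_interp(trend$porosity_pct, as.integer(days))
  sqrt(stats::var(signal) * (1 / r2 - 1))
}

#' Generate a 5-day phantom storage series
#'
#' Per-day phantoms follow the trend: target porosity interpolated between
#' the trend endpoints (monotonically increasing by default) and the body
#' shrunk by the relative volume trajectory `(V_d / V_1)^(1/3)` applied to
#' the base semi-axes. Covariates are generated as in
#' [simulate_storage_covariates()]. All randomness derives from `seed`
#' (day d uses sub-seed `seed + 1000 * d`).
#'
#' @param base A [phantom_spec()]; its semi-axes correspond to day 1.
#' @param days Number of storage days, default 5.
#' @param trend A [storage_trend()].
#' @param seed Integer seed.
#' @return A list of class `storage_series`: per-day elements each holding
#'   `phantom` (a `bun_phantom`) and `record` (one-row covariate
#'   data.frame), plus `covariates` (the full table with the true porosity
#'   and body volume appended).
#' @export
generate_storage_series <- function(base, days = 5L, trend = storage_trend(),
                                    seed = 1L) {
  stopifnot(inherits(base, "phantom_spec"))
  days <- as.integer(days)
  cov <- simulate_storage_covariates(days, trend, porosity_noise_sd = 0,
                                     seed = seed)
  por <- trend_interp(trend$porosity_pct, days)
  scale <- (trend_interp(trend$body_volume_mL, days) /
              trend$body_volume_mL[1])^(1 / 3)
  rscale <- trend_interp(trend$pore_radius_scale, days)
  out <- vector("list", days)
  for (d in seq_len(days)) {
    sp <- base
    sp$body_semi_axes_mm <- base$body_semi_axes_mm * scale[d]
    sp$target_porosity_pct <- por[d]
    sp$pore_count <- NULL
    sp$pore_radius_median_mm <- base$pore_radius_median_mm * rscale[d]
    sp$seed <- as.integer(seed + 1000L * d)
    ph <- generate_bun_phantom(sp)
    out[[d]] <- list(phantom = ph, record = cov[d, , drop = FALSE])
    cov$true_porosity_pct[d] <- ph$truth$true_porosity_pct
    cov$true_body_volume_mL[d] <- ph$truth$true_body_volume_mL
  }
  structure(list(days = out, covariates = cov), class = "storage_series")
}

#' @export
print.storage_series <- function(x, ...) {
  cat(sprintf("Storage series: %d days\n", length(x$days)))
  print(x$covariates, digits = 4)
  invisible(x)
}

#' Write the covariate table of a series as delimited text
#' @param series A `storage_series` (or its `covariates` data.frame).
#' @param path Output CSV path.
#' @export
write_covariates <- function(series, path) {
  df <- if (inherits(series, "storage_series")) series$covariates else series
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
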