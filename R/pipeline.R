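# Pipeline orchestration: structured config, the staged segmentation ->
# morphometry -> network -> statistics run, CSV outputs and a run manifest.
# Every constant with a printed field value (grayscale bands, opening
# radius, ROI side) is a config default, never a literal in the stages.

pipeline_defaults <- function() {
  list(
    input_raw = NULL,            # path to a RAW file (sidecar at <path>.meta)
    phantom = NULL,              # a phantom_spec for a single synthetic run
    series = NULL,               # list(base = phantom_spec, days =, trend =)
    matrix_band = c(-750, -250), # GSV band of the solid matrix
    pore_band = c(-1250, -1000), # GSV band of the pore/air phase (local ROI)
    auto_threshold = FALSE,      # balanced histogram threshold instead of band
    histogram_bin_width = 10,
    opening_radius_vox = 3.0,    # ball radius, voxels
    label_connectivity = 26,
    fill_connectivity = 6,
    feret_n_directions = 128,
    size_bin_edges_mm = c(0, 2, 4, 6, 8, 10),
    roi_side_vox = 45,
    roi_centers = NULL,          # list of 0-based voxel triples
    drop_border_pores = FALSE,
    network = TRUE,
    prune_factor = 1.0,
    stats = TRUE,
    moisture_region = "center",
    out_dir = NULL,              # NULL: nothing written, results returned only
    seed = 1L,
    verbose = TRUE)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration shared by all stages. Unknown
#' keys are rejected with the nearest valid name suggested. Defaults carry
#' the standard analysis constants for steamed-bread crumb: matrix band
#' -750..-250, pore band -1250..-1000, ball opening radius 3 voxels, local
#' ROI cubes of 45 voxels.
#'
#' @param ... Named settings overriding the defaults (see
#'   `crumbCT:::pipeline_defaults()` for the full list).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop("all configuration settings must be named")
  for (nm in names(args)) {
    if (!nm %in% names(cfg)) {
      near <- agrep(nm, names(cfg), max.distance = 0.4, value = TRUE)
      hint <- if (length(near)) paste0("; did you mean '", near[1], "'?") else ""
      stop("unknown configuration key '", nm, "'", hint)
    }
    cfg[[nm]] <- args[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$matrix_band) == 2L, length(cfg$pore_band) == 2L)
  if (cfg$matrix_band[1] > cfg$matrix_band[2]) stop("matrix_band: lo > hi")
  if (cfg$pore_band[1] > cfg$pore_band[2]) stop("pore_band: lo > hi")
  if (cfg$opening_radius_vox <= 0) stop("opening_radius_vox must be > 0")
  if (!cfg$label_connectivity %in% c(6, 26)) stop("label_connectivity must be 6 or 26")
  if (!cfg$fill_connectivity %in% c(6, 26)) stop("fill_connectivity must be 6 or 26")
  if (is.unsorted(cfg$size_bin_edges_mm, strictly = TRUE))
    stop("size_bin_edges_mm must be strictly increasing")
  if (cfg$roi_side_vox < 1) stop("roi_side_vox must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  n_inputs <- sum(!is.null(cfg$input_raw), !is.null(cfg$phantom),
                  !is.null(cfg$series))
  if (n_inputs > 1L)
    stop("give exactly one of input_raw, phantom, series")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror the [pipeline_config()] settings;
#'   `phantom` and `series$base` sub-maps are passed to [phantom_spec()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom)) y$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$series)) {
    y$series$base <- do.call(phantom_spec, y$series$base)
    if (!is.null(y$series$trend)) y$series$trend <- do.call(storage_trend, y$series$trend)
  }
  do.call(pipeline_config, y)
}

#' @export
print.pipeline_config <- function(x, ...) {
  src <- if (!is.null(x$input_raw)) paste("RAW", x$input_raw)
  else if (!is.null(x$phantom)) "synthetic phantom"
  else if (!is.null(x$series)) "synthetic storage series"
  else "(no input set)"
  cat(sprintf("Pipeline config: input %s; matrix band [%g, %g], opening radius %g vox, seed %d\n",
              src, x$matrix_band[1], x$matrix_band[2], x$opening_radius_vox,
              x$seed))
  invisible(x)
}

log_stage <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the segmentation chain on one volume
#'
#' Threshold the matrix band (or the balanced-histogram foreground), fill
#' enclosed cavities to recover the whole sample, subtract the matrix to
#' isolate interior pores, open with a ball to separate coalesced pores,
#' and label the separated pores. Voxel counts in and out of every stage
#' are logged so the chain is auditable.
#'
#' @param volume A [voxel_volume()].
#' @param config A [pipeline_config()].
#' @return A list: `histogram`, `matrix_mask`, `filled`, `pores`, `opened`,
#'   `labels`, `threshold` (the band or balanced threshold actually used).
#' @export
segment_volume <- function(volume, config = pipeline_config()) {
  stopifnot(inherits(volume, "voxel_volume"))
  hist <- compute_histogram(volume, config$histogram_bin_width)
  if (isTRUE(config$auto_threshold)) {
    thr <- balanced_histogram_threshold(hist)
    band <- c(thr, volume$meta$gsv_max)
    log_stage(config, "segment: balanced histogram threshold at GSV %d", thr)
  } else {
    band <- config$matrix_band
  }
  matrix_mask <- band_threshold(volume, band[1], band[2])
  log_stage(config, "segment: matrix band [%g, %g] -> %d voxels",
            band[1], band[2], sum(matrix_mask$grid))
  filled <- fill_holes(matrix_mask, config$fill_connectivity)
  log_stage(config, "segment: fill holes -> %d voxels (+%d)",
            sum(filled$grid), sum(filled$grid) - sum(matrix_mask$grid))
  pores <- mask_difference(filled, matrix_mask)
  log_stage(config, "segment: pore phase -> %d voxels", sum(pores$grid))
  opened <- binary_opening(pores, config$opening_radius_vox)
  log_stage(config, "segment: opening (ball r=%g) -> %d voxels",
            config$opening_radius_vox, sum(opened$grid))
  labels <- label_components(opened, config$label_connectivity)
  log_stage(config, "segment: %d separated pores", labels$n_labels)
  list(histogram = hist, matrix_mask = matrix_mask, filled = filled,
       pores = pores, opened = opened, labels = labels, threshold = band)
}

#' Analyze one volume end to end
#'
#' Segmentation chain, per-pore morphometry, summary, size distribution,
#' optional local-ROI pore fractions and optional pore-throat network.
#'
#' @param volume A [voxel_volume()].
#' @param config A [pipeline_config()].
#' @return A list: `segmentation`, `pore_stats`, `summary`,
#'   `size_distribution`, `roi` (data.frame or NULL), `network`,
#'   `network_summary` (or NULLs when disabled).
#' @export
analyze_volume <- function(volume, config = pipeline_config()) {
  seg <- segment_volume(volume, config)
  dirs <- feret_directions(config$feret_n_directions)
  stats <- measure_labels(seg$labels, directions = dirs)
  summ <- summarize_morphometry(stats, seg$pores, seg$filled,
                                drop_border_pores = config$drop_border_pores)
  sizes <- size_distribution(stats, config$size_bin_edges_mm)
  roi <- NULL
  if (!is.null(config$roi_centers)) {
    roi <- do.call(rbind, lapply(seq_along(config$roi_centers), function(i) {
      cube <- extract_cube_roi(volume, config$roi_centers[[i]],
                               config$roi_side_vox)
      data.frame(roi = i,
                 center = paste(config$roi_centers[[i]], collapse = " "),
                 pore_fraction_pct = local_pore_fraction(
                   cube, config$pore_band[1], config$pore_band[2]))
    }))
  }
  net <- net_summ <- NULL
  if (isTRUE(config$network)) {
    dm <- distance_transform(seg$pores)
    sk <- skeletonize(seg$pores)
    net <- skeleton_to_graph(sk, dm, config$prune_factor)
    net_summ <- network_summary(net)
    log_stage(config, "network: %d segments, mean throat %.3f mm",
              net_summ$n_segments, net_summ$mean_throat_radius_mm)
  }
  list(segmentation = seg, pore_stats = stats, summary = summ,
       size_distribution = sizes, roi = roi, network = net,
       network_summary = net_summ)
}

#' Run the full pipeline
#'
#' Resolves the configured input (RAW file, single phantom, or storage
#' series), runs [analyze_volume()] on each volume, runs the statistics
#' stage for series inputs (feature table, Pearson correlation matrix,
#' moisture-porosity linear fit), and, when `out_dir` is set, writes the
#' CSV tables and a YAML run manifest. Identical config and seed give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The result bundle, invisibly: for a single volume the
#'   [analyze_volume()] list; for a series additionally `covariates`,
#'   `feature_table`, `correlation`, `moisture_porosity_fit`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  set.seed(config$seed)
  out <- NULL
  if (!is.null(config$series)) {
    sr <- config$series
    series <- generate_storage_series(
      sr$base, days = if (is.null(sr$days)) 5L else sr$days,
      trend = if (is.null(sr$trend)) storage_trend() else sr$trend,
      seed = config$seed)
    analyses <- lapply(seq_along(series$days), function(d) {
      log_stage(config, "day %d:", d)
      analyze_volume(series$days[[d]]$phantom$volume, config)
    })
    summaries <- lapply(analyses, `[[`, "summary")
    ft <- build_feature_table(series$covariates, summaries,
                              config$moisture_region)
    stats_out <- NULL
    if (isTRUE(config$stats)) {
      cm <- correlation_matrix(ft[, setdiff(names(ft), "day")])
      fit <- linear_fit(ft$moisture_pct, ft$porosity_pct)
      stats_out <- list(correlation = cm, moisture_porosity_fit = fit)
    }
    out <- c(list(series = series, analyses = analyses,
                  covariates = series$covariates, feature_table = ft),
             stats_out)
  } else {
    volume <- if (!is.null(config$input_raw)) {
      read_raw(config$input_raw, paste0(config$input_raw, ".meta"))
    } else if (!is.null(config$phantom)) {
      ph <- generate_bun_phantom(config$phantom)
      ph$volume
    } else {
      stop("no input configured: set input_raw, phantom or series")
    }
    out <- analyze_volume(volume, config)
  }
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config, t0)
  invisible(out)
}

write_pipeline_outputs <- function(out, config, t0) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  write_one <- function(an, tag) {
    write_pore_stats(an$pore_stats, p(sprintf("pores_%s.csv", tag)))
    write.csv(as.data.frame(an$summary), p(sprintf("summary_%s.csv", tag)),
              row.names = FALSE)
    write.csv(an$size_distribution, p(sprintf("size_distribution_%s.csv", tag)),
              row.names = FALSE)
    write_histogram(an$segmentation$histogram, p(sprintf("histogram_%s.csv", tag)))
    if (!is.null(an$roi))
      write.csv(an$roi, p(sprintf("roi_%s.csv", tag)), row.names = FALSE)
    if (!is.null(an$network)) {
      write_network(an$network, p(sprintf("network_nodes_%s.csv", tag)),
                    p(sprintf("network_edges_%s.csv", tag)))
      write.csv(an$network_summary, p(sprintf("network_summary_%s.csv", tag)),
                row.names = FALSE)
    }
  }
  if (!is.null(out$analyses)) {
    for (d in seq_along(out$analyses))
      write_one(out$analyses[[d]], sprintf("day%d", d))
    write_covariates(out$covariates, p("covariates.csv"))
    write.csv(out$feature_table, p("feature_table.csv"), row.names = FALSE)
    if (!is.null(out$correlation))
      write_correlation_matrix(out$correlation, p("correlation_matrix.csv"))
    if (!is.null(out$moisture_porosity_fit)) {
      fit <- out$moisture_porosity_fit
      write.csv(data.frame(slope = fit$slope, intercept = fit$intercept,
                           r_squared = fit$r_squared, n = fit$n),
                p("moisture_porosity_fit.csv"), row.names = FALSE)
    }
  } else {
    write_one(out, "sample")
  }
  manifest <- list(
    package = "crumbCT",
    version = as.character(utils::packageVersion("crumbCT")),
    r_version = R.version.string,
    seed = config$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = config_echo(config))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(config$out_dir)
}

# config echo with phantom specs flattened to plain lists for YAML
config_echo <- function(config) {
  cfg <- unclass(config)
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  lapply(cfg, function(x) if (is.null(x)) NULL else strip(x))
}
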