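# End-to-end pipelines chaining the stages into the two workflows:
# tomography -> quantification, and scanning diffraction -> collagen maps.
# Configurations are validated, YAML round-trippable lists; runs emit a
# manifest with config hash, per-stage timings and checksummed outputs.

tomo_defaults <- function() list(
  pipeline = "tomography",
  phantom = list(shape_voxels = c(96L, 96L, 96L), n_trees = 2L,
                 rng_seed = 1L),
  n_angles = 200L,
  angle_span = 180,
  filter_name = "ramp",
  pad = "reflect",
  intensity_floor = 1e-6,
  delta = NULL, beta = NULL,      # default: vessel material of the phantom
  threshold = "otsu",
  min_component_voxels = 27L,
  opening = TRUE,
  axis = "z",
  classes = list(),
  min_branch_length = 5,
  keep_volume = FALSE,
  out_dir = NULL)

diffraction_defaults <- function() list(
  pipeline = "diffraction",
  base_spec = list(),
  grid = list(nx = 4L, ny = 4L, amount = 1, angle = 30, degree = 0.6),
  q_window = c(4.6, 6.6),
  background = "poly2",
  n_radial_bins = 150L,
  n_phi_bins = 72L,
  out_dir = NULL)

merge_config <- function(defaults, args, what) {
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s config key(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  modifyList(defaults, args, keep.null = TRUE)
}

#' Configuration for the tomography-quantification pipeline
#'
#' Unknown keys are rejected; the result round-trips losslessly through
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ... overrides of the default fields: `phantom` (arguments to
#'   [phantom_spec()]), `n_angles`, `angle_span` (degrees), `filter_name`,
#'   `pad`, `intensity_floor`, `delta`/`beta` (retrieval material; default
#'   the phantom's vessel material), `threshold`, `min_component_voxels`,
#'   `opening`, `axis`, `classes` (arguments to [size_class_config()]),
#'   `min_branch_length`, `keep_volume`, `out_dir`
#' @return a validated config list of class `pipeline_config`
#' @export
tomo_config <- function(...) {
  cfg <- merge_config(tomo_defaults(), list(...), "tomography")
  structure(cfg, class = "pipeline_config")
}

#' Configuration for the diffraction-mapping pipeline
#'
#' @param ... overrides of the default fields: `base_spec` (arguments to
#'   [diffraction_sim_spec()]), `grid` (`nx`, `ny` and scalar-or-matrix
#'   `amount`, `angle`, `degree`), `q_window`, `background`,
#'   `n_radial_bins`, `n_phi_bins`, `out_dir`
#' @return a validated config list of class `pipeline_config`
#' @export
diffraction_config <- function(...) {
  cfg <- merge_config(diffraction_defaults(), list(...), "diffraction")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a `pipeline_config`
#' @param path YAML file path
#' @return `path` (write) or the validated config (read)
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$pipeline))
    stop("config is missing the 'pipeline' field")
  maker <- switch(raw$pipeline, tomography = tomo_config,
                  diffraction = diffraction_config,
                  stop("unknown pipeline kind: ", raw$pipeline))
  do.call(maker, raw[setdiff(names(raw), "pipeline")])
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

run_stage <- function(name, timings, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
  timings[[name]] <- proc.time()[["elapsed"]] - t0
  list(value = value, timings = timings)
}

manifest_outputs <- function(paths) {
  if (length(paths) == 0)
    return(data.frame(file = character(), md5 = character()))
  data.frame(file = unname(paths), md5 = unname(tools::md5sum(paths)))
}

#' Run the tomography-quantification pipeline
#'
#' Phantom generation, per-slice thickness projection, linearized forward
#' propagation, single-distance phase retrieval, filtered back projection,
#' vessel segmentation, depth-profile counting, skeletonization and sample
#' summary, all driven by one seeded configuration. Stage failures abort
#' with the stage named in the error.
#'
#' @param config a [tomo_config()]
#' @return list with `truth`, `mask`, `profile`, `graph`, `summary`,
#'   `manifest` (and `volume`/`recon` when `keep_volume` is `TRUE`); files
#'   are written under `out_dir` when set
#' @export
run_tomo_pipeline <- function(config = tomo_config()) {
  stopifnot(inherits(config, "pipeline_config"),
            config$pipeline == "tomography")
  timings <- list()

  st <- run_stage("phantom", timings, {
    generate_phantom(do.call(phantom_spec, config$phantom))
  })
  ph <- st$value; timings <- st$timings
  vol <- ph$volume
  vs <- vol$voxel_size
  n <- dim(vol$labels)[1]
  nz <- dim(vol$labels)[3]
  if (dim(vol$labels)[2] != n)
    stop("pipeline stage 'phantom' failed: slices must be square")

  mat <- vol$materials$vessel
  g <- imaging_geometry(
    energy_kev = 24, distance = 5e4, pixel_size = vs,
    delta = if (is.null(config$delta)) mat$delta else config$delta,
    beta = if (is.null(config$beta)) mat$beta else config$beta)
  angles <- seq(0, config$angle_span,
                length.out = config$n_angles + 1)[-(config$n_angles + 1)]

  st <- run_stage("project", timings, {
    vessel <- vol$labels == 2L
    sinos <- array(0, c(n, config$n_angles, nz))
    rad <- angles * pi / 180
    for (k in seq_len(nz))
      sinos[, , k] <- .radon_cpp(vessel[, , k] + 0, rad) * vs
    sinos
  })
  sinos <- st$value; timings <- st$timings

  st <- run_stage("propagate_retrieve", timings, {
    retr <- array(0, dim(sinos))
    for (a in seq_len(config$n_angles)) {
      intens <- forward_propagate(sinos[, a, ], g, pad = config$pad)
      intens <- pmax(intens, config$intensity_floor)
      retr[, a, ] <- paganin_retrieve(intens, g, pad = config$pad)
    }
    retr
  })
  retr <- st$value; timings <- st$timings

  st <- run_stage("reconstruct", timings, {
    recon <- array(0, c(n, n, nz))
    for (k in seq_len(nz))
      recon[, , k] <- fbp_reconstruct(retr[, , k], angles,
                                      filter_name = config$filter_name,
                                      pixel_size = vs)
    recon
  })
  recon <- st$value; timings <- st$timings

  st <- run_stage("segment", timings, {
    segment_vessels(recon, voxel_size = vs, threshold = config$threshold,
                    min_component_voxels = config$min_component_voxels,
                    opening = config$opening)
  })
  mask <- st$value; timings <- st$timings

  classes <- do.call(size_class_config, config$classes)
  st <- run_stage("quantify", timings, {
    profile <- per_slice_counts(mask, axis = config$axis, classes = classes)
    graph <- skeletonize_3d(mask)
    summary <- summarize_sample(mask, profile, graph, classes,
                                min_branch_length = config$min_branch_length)
    list(profile = profile, graph = graph, summary = summary)
  })
  quant <- st$value; timings <- st$timings

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(config$out_dir, "depth_profile.csv")
    write_profile_csv(quant$profile, p1)
    p2 <- file.path(config$out_dir, "quant_summary.json")
    write_summary_json(quant$summary, p2)
    p3 <- file.path(config$out_dir, "skeleton_edges.csv")
    write_skeleton_csv(quant$graph, p3)
    p4 <- file.path(config$out_dir, "truth.csv")
    write_truth_csv(ph$truth, p4)
    paths <- c(p1, p2, p3, p4)
  }

  manifest <- list(pipeline = "tomography",
                   package_version = as.character(
                     utils::packageVersion("microvasq")),
                   config_hash = config_hash(config),
                   timings_s = lapply(timings, round, 3),
                   outputs = manifest_outputs(paths))
  out <- list(truth = ph$truth, mask = mask, profile = quant$profile,
              graph = quant$graph, summary = quant$summary,
              manifest = manifest, config = config)
  if (isTRUE(config$keep_volume)) {
    out$volume <- vol
    out$recon <- recon
  }
  out
}

expand_map <- function(x, nx, ny, field) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(nx, ny)))
      stop_field(field, sprintf("must be %d x %d", nx, ny))
    return(x)
  }
  if (length(x) == 1) return(matrix(x, nx, ny))
  stop_field(field, "must be a scalar or an nx x ny matrix")
}

#' Run the diffraction-mapping pipeline
#'
#' Simulates (or accepts) a scan grid of diffraction patterns, integrates
#' and fits every position and assembles the collagen amount / orientation
#' angle / orientation degree maps.
#'
#' @param config a [diffraction_config()]
#' @param scan optional pre-built `diffraction_scan` (overrides the
#'   simulated grid)
#' @return list with `scan`, `map` and `manifest`
#' @export
run_diffraction_pipeline <- function(config = diffraction_config(),
                                     scan = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            config$pipeline == "diffraction")
  timings <- list()

  if (is.null(scan)) {
    st <- run_stage("simulate", timings, {
      base <- do.call(diffraction_sim_spec, config$base_spec)
      nx <- config$grid$nx; ny <- config$grid$ny
      simulate_scan_grid(
        base,
        amount_map = expand_map(config$grid$amount, nx, ny, "grid$amount"),
        angle_map = expand_map(config$grid$angle, nx, ny, "grid$angle"),
        degree_map = expand_map(config$grid$degree, nx, ny, "grid$degree"))
    })
    scan <- st$value; timings <- st$timings
  }

  st <- run_stage("fit_map", timings, {
    build_collagen_map(scan, q_window = config$q_window,
                       background = config$background,
                       n_radial_bins = config$n_radial_bins,
                       n_phi_bins = config$n_phi_bins)
  })
  cmap <- st$value; timings <- st$timings

  paths <- character(0)
  if (!is.null(config$out_dir)) {
    paths <- write_collagen_map(cmap, config$out_dir)
  }

  manifest <- list(pipeline = "diffraction",
                   package_version = as.character(
                     utils::packageVersion("microvasq")),
                   config_hash = config_hash(config),
                   timings_s = lapply(timings, round, 3),
                   outputs = manifest_outputs(paths))
  list(scan = scan, map = cmap, manifest = manifest, config = config)
}
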