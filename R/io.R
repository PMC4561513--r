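# Plain-format I/O: multi-page TIFF volumes and float TIFF patterns with
# JSON sidecars, CSV truth/profile/skeleton tables, JSON summaries.
# Grayscale data are rescaled to [0,1] for TIFF storage; the affine scale
# is recorded in the sidecar so reads are lossless up to float precision.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a volume as a multi-page TIFF with a JSON sidecar
#'
#' Label volumes are stored as 8-bit pages (one per z slice); grayscale
#' volumes as 32-bit float pages rescaled to `[0, 1]` with the scale
#' recorded in the sidecar.
#'
#' @param volume a `labeled_volume` or a numeric 3D array
#' @param path output TIFF path; the sidecar goes to the same name with a
#'   `.json` extension
#' @param voxel_size required for plain array input, micrometers
#' @return `path`, invisibly
#' @export
write_volume_tiff <- function(volume, path, voxel_size = NULL) {
  if (inherits(volume, "labeled_volume")) {
    labels <- volume$labels
    pages <- lapply(seq_len(dim(labels)[3]),
                    function(k) labels[, , k] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    meta <- list(kind = "labels", voxel_size_um = volume$voxel_size,
                 shape = dim(labels), materials = volume$materials)
  } else {
    stopifnot(length(dim(volume)) == 3L)
    if (is.null(voxel_size)) stop("voxel_size required for array input")
    rng <- range(volume)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(dim(volume)[3]),
                    function(k) (volume[, , k] - rng[1]) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(kind = "grayscale", voxel_size_um = voxel_size,
                 shape = dim(volume), offset = rng[1], scale = scale)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path TIFF path (sidecar expected alongside)
#' @return a `labeled_volume` or a numeric array with attribute
#'   `voxel_size`
#' @export
read_volume_tiff <- function(path) {
  meta <- read_sidecar(path, c("kind", "voxel_size_um", "shape"))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, unlist(meta$shape))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (meta$kind == "labels") {
    labs <- array(as.integer(round(arr * 255)), dim(arr))
    mats <- lapply(meta$materials, function(m)
      list(delta = m$delta, beta = m$beta))
    labeled_volume(labs, meta$voxel_size_um, mats)
  } else {
    out <- arr * meta$scale + meta$offset
    attr(out, "voxel_size") <- meta$voxel_size_um
    out
  }
}

read_sidecar <- function(path, required) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sidecar ", sc, " is missing required field(s): ",
         paste(missing, collapse = ", "))
  meta
}

#' Write vessel centerline truth as CSV (+ JSON sidecar)
#'
#' One row per polyline point: `tree`, `segment`, `parent`, `point`, `x`,
#' `y`, `z` (um), `radius` (um); extent and voxel size go to the sidecar.
#'
#' @param truth a `vessel_tree_truth`
#' @param path CSV output path
#' @return `path`, invisibly
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "vessel_tree_truth"))
  write.csv(truth$points, path, row.names = FALSE)
  jsonlite::write_json(list(extent_um = truth$extent_um,
                            voxel_size_um = truth$voxel_size,
                            entry_face = truth$entry_face),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read vessel centerline truth written by [write_truth_csv()]
#' @param path CSV path
#' @return a `vessel_tree_truth`
#' @export
read_truth_csv <- function(path) {
  meta <- read_sidecar(path, c("extent_um", "voxel_size_um"))
  pts <- read.csv(path)
  structure(list(points = pts, extent_um = unlist(meta$extent_um),
                 voxel_size = meta$voxel_size_um,
                 entry_face = meta$entry_face),
            class = "vessel_tree_truth")
}

#' Write a diffraction pattern as 32-bit float TIFF with geometry sidecar
#' @param pattern detector image matrix (geometry attribute used if `geom`
#'   is not given)
#' @param path TIFF output path
#' @param geom a [detector_geometry()]
#' @return `path`, invisibly
#' @export
write_pattern_tiff <- function(pattern, path,
                               geom = attr(pattern, "geometry")) {
  if (is.null(geom)) stop("detector geometry required")
  rng <- range(pattern)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((pattern - rng[1]) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(wavelength_nm = geom$wavelength_nm,
                            distance_mm = geom$distance_mm,
                            pixel_size_mm = geom$pixel_size_mm,
                            detector_px = geom$detector_px,
                            beam_center = geom$beam_center,
                            offset = rng[1], scale = scale),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a diffraction pattern written by [write_pattern_tiff()]
#'
#' Fails with the offending field named if the geometry sidecar is
#' incomplete.
#'
#' @param path TIFF path
#' @return pattern matrix with `geometry` attribute
#' @export
read_pattern_tiff <- function(path) {
  meta <- read_sidecar(path, c("wavelength_nm", "distance_mm",
                               "pixel_size_mm", "detector_px",
                               "beam_center", "offset", "scale"))
  img <- tiff::readTIFF(path)
  out <- img * meta$scale + meta$offset
  attr(out, "geometry") <- detector_geometry(
    wavelength_nm = meta$wavelength_nm, distance_mm = meta$distance_mm,
    pixel_size_mm = meta$pixel_size_mm,
    detector_px = unlist(meta$detector_px),
    beam_center = unlist(meta$beam_center))
  out
}

#' Write a depth profile as CSV
#' @param profile a `depth_profile`
#' @param path CSV output path
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a quantitative summary as JSON
#' @param summary a `quant_summary`
#' @param path JSON output path
#' @return `path`, invisibly
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a skeleton edge list as CSV
#'
#' One row per edge with endpoint node coordinates (um) and path length.
#'
#' @param g a `skeleton_graph`
#' @param path CSV output path
#' @return `path`, invisibly
#' @export
write_skeleton_csv <- function(g, path) {
  stopifnot(inherits(g, "skeleton_graph"))
  e <- g$edges
  n <- g$nodes
  df <- data.frame(edge = e$id,
                   from = e$from, to = e$to,
                   x1 = n$x[e$from], y1 = n$y[e$from], z1 = n$z[e$from],
                   x2 = n$x[e$to], y2 = n$y[e$to], z2 = n$z[e$to],
                   length_um = e$length_um, n_voxels = e$n_voxels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a collagen map as rasters (TIFF) plus a vector table (CSV)
#' @param cmap a `collagen_map`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return character vector of written paths, invisibly
#' @export
write_collagen_map <- function(cmap, dir, prefix = "collagen") {
  stopifnot(inherits(cmap, "collagen_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (what in c("amount", "angle", "degree")) {
    m <- cmap[[what]]
    m[!is.finite(m)] <- 0
    rng <- range(m)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, what))
    tiff::writeTIFF((m - rng[1]) / scale, p, bits.per.sample = 32L)
    jsonlite::write_json(list(kind = what, offset = rng[1], scale = scale),
                         sidecar_path(p), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  pv <- file.path(dir, sprintf("%s_vectors.csv", prefix))
  write.csv(cmap$table, pv, row.names = FALSE)
  invisible(c(paths, pv))
}
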