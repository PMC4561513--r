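# Vessel segmentation of reconstructed grayscale volumes.

#' Binary vessel mask container
#'
#' @param mask logical 3D array
#' @param voxel_size voxel size, micrometers
#' @param provenance list recording how the mask was obtained
#' @return object of class `vessel_mask`
#' @export
vessel_mask <- function(mask, voxel_size, provenance = list()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  check_scalar_positive(voxel_size, "voxel_size")
  structure(list(mask = mask, voxel_size = voxel_size,
                 provenance = provenance), class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("vessel_mask: %dx%dx%d @ %.3g um, %d foreground voxels\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$mask)))
  invisible(x)
}

#' Segment vessels in a reconstructed volume
#'
#' Global thresholding (Otsu by default, or a fixed value), followed by a
#' radius-1 morphological opening and removal of 26-connected components
#' smaller than `min_component_voxels`. A constant (zero dynamic range)
#' volume yields an empty mask rather than an arbitrary Otsu split. An
#' all-background result is allowed and returned as an empty mask.
#'
#' @param volume 3D numeric array (reconstructed grayscale) or a
#'   `labeled_volume`
#' @param voxel_size voxel size in micrometers (taken from a
#'   `labeled_volume` input automatically)
#' @param threshold `"otsu"` or a fixed numeric threshold; voxels strictly
#'   above the threshold are foreground
#' @param min_component_voxels discard 26-connected components smaller than
#'   this many voxels
#' @param opening apply the radius-1 opening (default `TRUE`)
#' @return a [vessel_mask()]
#' @export
segment_vessels <- function(volume, voxel_size = NULL, threshold = "otsu",
                            min_component_voxels = 27L, opening = TRUE) {
  if (inherits(volume, "labeled_volume")) {
    if (is.null(voxel_size)) voxel_size <- volume$voxel_size
    volume <- volume$labels
  }
  if (is.null(voxel_size))
    stop("voxel_size must be given for a plain array input")
  stopifnot(length(dim(volume)) == 3L)
  if (!all(is.finite(volume))) stop("volume contains non-finite voxels")

  if (identical(threshold, "otsu")) {
    rng <- range(volume)
    if (diff(rng) == 0) {
      mask <- array(FALSE, dim(volume))
      return(vessel_mask(mask, voxel_size,
                         list(threshold = NA_real_, method = "otsu",
                              note = "constant volume")))
    }
    norm <- (volume - rng[1]) / diff(rng)
    # reshape so one global threshold is computed over all voxels
    thr01 <- EBImage::otsu(matrix(norm, nrow = dim(volume)[1]),
                           range = c(0, 1))
    thr <- rng[1] + thr01 * diff(rng)
    method <- "otsu"
  } else {
    check_scalar_positive(abs(threshold) + 1, "threshold") # numeric scalar
    thr <- threshold
    method <- "fixed"
  }

  mask <- volume > thr
  if (opening && any(mask)) mask <- open3d(mask)
  if (any(mask) && min_component_voxels > 1) {
    lab <- .label_components_cpp(as.vector(mask), dim(mask), 26L)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component_voxels)
    mask <- array(lab %in% keep & lab > 0L, dim(mask))
  }
  vessel_mask(mask, voxel_size,
              list(threshold = thr, method = method,
                   min_component_voxels = min_component_voxels,
                   opening = opening))
}

#' Per-slice vessel counts by diameter class
#'
#' For each slice perpendicular to `axis`, 8-connected 2D components are
#' extracted; each component's area `A` (voxels times pixel area) gives an
#' equivalent circular diameter `d = 2 sqrt(A / pi)`, which assigns it to
#' the small class, the large class, or neither. Components of any size
#' count toward `v_total`, so `v_total >= v_small + v_large`. Diameters of
#' vessels crossing the slice obliquely are inflated by the section tilt
#' (by about `1/sqrt(cos(angle))`); counts are unaffected.
#'
#' @param mask a [vessel_mask()]
#' @param axis slicing axis (`"x"`, `"y"`, `"z"`)
#' @param classes a [size_class_config()]
#' @return a `depth_profile` data frame (columns `slice`, `depth_um`,
#'   `v_small`, `v_large`, `v_total`) whose `sections` attribute lists the
#'   component areas (um^2) per slice
#' @export
per_slice_counts <- function(mask, axis = "z", classes = size_class_config()) {
  stopifnot(inherits(mask, "vessel_mask"))
  vs <- mask$voxel_size
  a <- axis_last(mask$mask, axis)
  nz <- dim(a)[3]
  px_area <- vs^2
  v_small <- v_large <- v_total <- integer(nz)
  sections <- vector("list", nz)
  for (k in seq_len(nz)) {
    sl <- a[, , k]
    if (!any(sl)) {
      sections[[k]] <- numeric(0)
      next
    }
    lab <- .label_components_cpp(as.vector(sl), c(dim(sl), 1L), 26L)
    areas <- tabulate(lab) * px_area
    dia <- 2 * sqrt(areas / pi)
    v_total[k] <- length(areas)
    v_small[k] <- sum(dia >= classes$small_range[1] &
                        dia < classes$small_range[2])
    v_large[k] <- sum(dia >= classes$large_range[1] &
                        dia <= classes$large_range[2])
    sections[[k]] <- areas
  }
  new_depth_profile(v_small, v_large, v_total, vs, axis,
                    source = "mask", sections = sections)
}
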