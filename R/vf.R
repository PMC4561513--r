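# Vessel size classes and the vascularization factor.
#
# Vessels crossing a section are classed by equivalent diameter into small
# (10-15 um) and large (15-20 um) calibers. The vascularization factor is
# the depth integral of the two class counts, each weighted by its average
# cross-section area, normalized by a total depth, and is a proxy for
# network flow capacity under the assumption that flow scales with vessel
# section:
#   VF = [ S_small * int V_m(z) dz + S_large * int V_M(z) dz ] / D_norm.

#' Default section weight of a diameter class
#'
#' Area of the circle at the class-midpoint diameter,
#' `pi * ((lo + hi) / 4)^2`, rounded by the reporting convention used for
#' the class weights: nearest integer below 200 um^2, two significant
#' figures above. The 10-15 um class gives 123 um^2 and the 15-20 um class
#' 240 um^2.
#'
#' @param d_range diameter range `(lo, hi)` in micrometers, `0 < lo < hi`
#' @param round apply the reporting rounding (default `TRUE`); with
#'   `FALSE` the exact midpoint-circle area is returned
#' @return section weight in um^2
#' @examples
#' default_section_weight(c(10, 15)) # 123
#' default_section_weight(c(15, 20)) # 240
#' @export
default_section_weight <- function(d_range, round = TRUE) {
  if (!is.numeric(d_range) || length(d_range) != 2L ||
      d_range[1] <= 0 || d_range[1] >= d_range[2])
    stop("d_range must satisfy 0 < lo < hi")
  w <- pi * ((d_range[1] + d_range[2]) / 4)^2
  if (!round) return(w)
  if (w < 200) round(w) else signif(w, 2)
}

#' Vessel size-class configuration
#'
#' Diameter classes are half-open on the left boundary: a vessel of exactly
#' 15 um equivalent diameter is large. Section weights default to the
#' circle area at the class-midpoint diameter, kept at full precision
#' internally (the rounded reporting values are available through
#' [default_section_weight()]).
#'
#' @param small_range small-class diameter range, um
#' @param large_range large-class diameter range, um; must start where the
#'   small class ends
#' @param small_section,large_section section weights, um^2 (default:
#'   midpoint circle areas)
#' @param total_depth_norm normalization depth for the vascularization
#'   factor, um; `NULL` (default) normalizes by the analyzed depth of the
#'   profile, while 1400 reproduces the fixed-depth convention used when
#'   comparing samples spanning slightly different depths
#' @return object of class `size_class_config`
#' @export
size_class_config <- function(small_range = c(10, 15),
                              large_range = c(15, 20),
                              small_section = NULL,
                              large_section = NULL,
                              total_depth_norm = NULL) {
  check_range(small_range, "small_range")
  check_range(large_range, "large_range")
  if (small_range[2] != large_range[1])
    stop_field("large_range", "classes must be contiguous and non-overlapping")
  if (is.null(small_section))
    small_section <- default_section_weight(small_range, round = FALSE)
  if (is.null(large_section))
    large_section <- default_section_weight(large_range, round = FALSE)
  check_scalar_positive(small_section, "small_section")
  check_scalar_positive(large_section, "large_section")
  if (!is.null(total_depth_norm))
    check_scalar_positive(total_depth_norm, "total_depth_norm")
  structure(list(small_range = small_range, large_range = large_range,
                 small_section = small_section, large_section = large_section,
                 total_depth_norm = total_depth_norm),
            class = "size_class_config")
}

#' @export
print.size_class_config <- function(x, ...) {
  cat(sprintf(
    "size classes: small [%g, %g) um (S = %.4g um^2), large [%g, %g] um (S = %.4g um^2)\n",
    x$small_range[1], x$small_range[2], x$small_section,
    x$large_range[1], x$large_range[2], x$large_section))
  invisible(x)
}

#' Vascularization factor of a depth profile
#'
#' Section-weighted depth integral of the class counts normalized by the
#' total depth (units um^2): class count integrals are slice sums times the
#' slice thickness. With the normalization depth equal to the analyzed
#' depth, a single small vessel present in every slice gives exactly the
#' small-class section weight.
#'
#' @param profile a `depth_profile` (from [per_slice_counts()] or
#'   [truth_depth_profile()])
#' @param classes a [size_class_config()]; its `total_depth_norm` (or the
#'   analyzed depth when `NULL`) sets the normalization
#' @return the vascularization factor, um^2
#' @export
vascularization_factor <- function(profile, classes = size_class_config()) {
  stopifnot(inherits(profile, "depth_profile"))
  dz <- attr(profile, "slice_thickness")
  if (is.null(dz) || !is.finite(dz) || dz <= 0)
    stop("profile slice thickness unknown")
  d_norm <- classes$total_depth_norm
  if (is.null(d_norm)) d_norm <- nrow(profile) * dz
  if (d_norm <= 0) stop("total_depth_norm must be positive")
  (classes$small_section * sum(profile$v_small) * dz +
      classes$large_section * sum(profile$v_large) * dz) / d_norm
}

#' Per-sample quantitative summary
#'
#' Collects the headline readouts of one analyzed volume: largest per-slice
#' component section, smallest classed equivalent diameter, branch count,
#' class count totals, and the vascularization factor.
#'
#' @param mask a [vessel_mask()]
#' @param profile the matching `depth_profile` from [per_slice_counts()]
#' @param graph the matching `skeleton_graph`
#' @param classes a [size_class_config()]
#' @param min_branch_length spur-pruning threshold passed to
#'   [count_branches()], um
#' @return object of class `quant_summary`: `max_section_um2`,
#'   `min_diameter_um`, `n_branches`, `total_v_small`, `total_v_large`,
#'   `vf_um2`
#' @export
summarize_sample <- function(mask, profile, graph,
                             classes = size_class_config(),
                             min_branch_length = 5) {
  stopifnot(inherits(profile, "depth_profile"))
  sections <- attr(profile, "sections")
  all_areas <- if (is.null(sections)) numeric(0) else unlist(sections)
  dia <- 2 * sqrt(all_areas / pi)
  classed <- dia[dia >= classes$small_range[1] &
                   dia <= classes$large_range[2]]
  structure(list(
    max_section_um2 = if (length(all_areas)) max(all_areas) else 0,
    min_diameter_um = if (length(classed)) min(classed) else 0,
    n_branches = if (is.null(graph)) 0L else
      count_branches(graph, min_branch_length),
    total_v_small = sum(profile$v_small),
    total_v_large = sum(profile$v_large),
    vf_um2 = vascularization_factor(profile, classes)
  ), class = "quant_summary")
}

#' @export
print.quant_summary <- function(x, ...) {
  cat("quant_summary:\n")
  cat(sprintf("  max section       %.4g um^2\n", x$max_section_um2))
  cat(sprintf("  min diameter      %.4g um\n", x$min_diameter_um))
  cat(sprintf("  branches          %d\n", x$n_branches))
  cat(sprintf("  total small (V_m) %d\n", x$total_v_small))
  cat(sprintf("  total large (V_M) %d\n", x$total_v_large))
  cat(sprintf("  VF                %.4g um^2\n", x$vf_um2))
  invisible(x)
}
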