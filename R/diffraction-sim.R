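# Synthetic 2D scanning-diffraction patterns with known collagen-peak and
# orientation parameters, the forward model validating the fitting stage.
#
# Each pattern is an isotropic background plus an equatorial ring,
#   I(q, Phi) = B(q) + A exp(-(q - q_c)^2 / (2 sigma_q^2)) * w(Phi),
#   w(Phi) = (1 - f) + f * [wrapped Gaussians at Phi0 and Phi0 + 180],
# on a detector mapped to q via q = 4 pi sin(theta) / lambda with
# 2 theta = atan(r / L). Optional Poisson noise on the counts.

#' Specification of a synthetic diffraction pattern
#'
#' The default geometry mirrors a transmission setup with a 0.0976 nm
#' wavelength and a 110 cm sample-detector distance; the synthetic detector
#' is a coarse grid whose q range comfortably brackets the collagen
#' equatorial ring near 5.6 1/nm.
#'
#' @param detector_px detector size in pixels `(n, m)`
#' @param pixel_size_mm pixel pitch, mm
#' @param distance_mm sample-detector distance, mm
#' @param wavelength_nm wavelength, nm
#' @param q_c true ring position, 1/nm (must lie in the instrument range
#'   0.5-30 1/nm)
#' @param sigma_q true ring width, 1/nm
#' @param amplitude ring peak amplitude, counts
#' @param background isotropic background: `list(model = "poly2",
#'   coeffs = c(c0, c1, c2))` or `list(model = "powerlaw",
#'   coeffs = c(a, k))` for `a * q^-k`
#' @param orientation_angle preferred azimuthal orientation, degrees
#' @param orientation_sigma azimuthal peak width, degrees
#' @param aligned_fraction fraction of aligned material in `[0, 1]`
#'   (0 gives an isotropic ring)
#' @param poisson_noise apply Poisson counting noise
#' @param rng_seed seed used when noise is on
#' @return object of class `diffraction_sim_spec`
#' @export
diffraction_sim_spec <- function(detector_px = c(256L, 256L),
                                 pixel_size_mm = 1.1,
                                 distance_mm = 1100,
                                 wavelength_nm = 0.0976,
                                 q_c = 5.6,
                                 sigma_q = 0.35,
                                 amplitude = 200,
                                 background = list(model = "poly2",
                                                   coeffs = c(150, -12, 0.3)),
                                 orientation_angle = 30,
                                 orientation_sigma = 25,
                                 aligned_fraction = 0.6,
                                 poisson_noise = TRUE,
                                 rng_seed = 1L) {
  if (!is.numeric(detector_px) || length(detector_px) != 2L ||
      any(detector_px < 16))
    stop_field("detector_px", "must be two integers >= 16")
  check_scalar_positive(pixel_size_mm, "pixel_size_mm")
  check_scalar_positive(distance_mm, "distance_mm")
  check_scalar_positive(wavelength_nm, "wavelength_nm")
  if (!is.numeric(q_c) || q_c < 0.5 || q_c > 30)
    stop_field("q_c", "must lie within the instrument q range [0.5, 30] 1/nm")
  check_scalar_positive(sigma_q, "sigma_q")
  if (!is.numeric(amplitude) || amplitude < 0)
    stop_field("amplitude", "must be non-negative")
  if (!is.list(background) || !background$model %in% c("poly2", "powerlaw"))
    stop_field("background", "model must be 'poly2' or 'powerlaw'")
  if (!is.numeric(aligned_fraction) || aligned_fraction < 0 ||
      aligned_fraction > 1)
    stop_field("aligned_fraction", "must be in [0, 1]")
  check_scalar_positive(orientation_sigma, "orientation_sigma")
  structure(list(detector_px = as.integer(detector_px),
                 pixel_size_mm = pixel_size_mm, distance_mm = distance_mm,
                 wavelength_nm = wavelength_nm, q_c = q_c, sigma_q = sigma_q,
                 amplitude = amplitude, background = background,
                 orientation_angle = orientation_angle,
                 orientation_sigma = orientation_sigma,
                 aligned_fraction = aligned_fraction,
                 poisson_noise = isTRUE(poisson_noise),
                 rng_seed = as.integer(rng_seed)),
            class = "diffraction_sim_spec")
}

sim_geometry <- function(spec) {
  detector_geometry(wavelength_nm = spec$wavelength_nm,
                    distance_mm = spec$distance_mm,
                    pixel_size_mm = spec$pixel_size_mm,
                    detector_px = spec$detector_px)
}

eval_background <- function(background, q) {
  co <- background$coeffs
  if (background$model == "poly2") {
    co[1] + co[2] * q + co[3] * q^2
  } else {
    # power law diverges at the beam center; floor q at a small value
    co[1] * pmax(q, 0.05)^(-co[2])
  }
}

# pair of wrapped Gaussians at delta = 0 and 180 (delta in degrees relative
# to the orientation angle), copies at +-360 included so the profile is
# exactly 360-periodic for the widths of interest
wrapped_pair <- function(delta, sigma) {
  d <- wrap180(delta)
  out <- 0
  for (j in c(-2, -1, 0, 1, 2)) out <- out + exp(-(d + 180 * j)^2 / (2 * sigma^2))
  out
}

#' Simulate one 2D diffraction pattern
#'
#' @param spec a [diffraction_sim_spec()]
#' @return numeric matrix of detector counts with attributes `geometry`
#'   (the [detector_geometry()]) and `spec`
#' @examples
#' p <- simulate_diffraction_pattern(
#'   diffraction_sim_spec(poisson_noise = FALSE))
#' dim(p)
#' @export
simulate_diffraction_pattern <- function(spec) {
  stopifnot(inherits(spec, "diffraction_sim_spec"))
  geom <- sim_geometry(spec)
  maps <- q_map(geom)
  if (spec$q_c > max(maps$q))
    stop(sprintf(
      "q_c = %.3g 1/nm lies outside the detector coverage (max %.3g 1/nm)",
      spec$q_c, max(maps$q)))
  bg <- eval_background(spec$background, maps$q)
  ring <- spec$amplitude * exp(-(maps$q - spec$q_c)^2 / (2 * spec$sigma_q^2))
  w <- (1 - spec$aligned_fraction) +
    spec$aligned_fraction * wrapped_pair(maps$phi - spec$orientation_angle,
                                         spec$orientation_sigma)
  intensity <- pmax(bg + ring * w, 0)
  if (spec$poisson_noise) {
    intensity <- withr::with_seed(
      spec$rng_seed,
      matrix(rpois(length(intensity), intensity), nrow(intensity)))
  }
  attr(intensity, "geometry") <- geom
  attr(intensity, "spec") <- spec
  intensity
}

#' Simulate a scan grid of diffraction patterns
#'
#' One pattern per scan position, with the ring amplitude scaled by
#' `amount_map`, the orientation angle set by `angle_map` (degrees) and the
#' aligned fraction set by `degree_map`. Each position gets its own noise
#' seed derived from the base seed, so grids are reproducible.
#'
#' @param base_spec a [diffraction_sim_spec()] providing geometry, ring and
#'   background parameters
#' @param amount_map,angle_map,degree_map numeric matrices of identical
#'   shape
#' @return object of class `diffraction_scan`: list of patterns in
#'   column-major scan order plus the grid shape and geometry
#' @export
simulate_scan_grid <- function(base_spec, amount_map, angle_map, degree_map) {
  stopifnot(inherits(base_spec, "diffraction_sim_spec"))
  if (!all(dim(amount_map) == dim(angle_map)) ||
      !all(dim(amount_map) == dim(degree_map)))
    stop("amount_map, angle_map and degree_map must share the same shape")
  nxy <- dim(amount_map)
  patterns <- vector("list", length(amount_map))
  for (i in seq_along(amount_map)) {
    sp <- base_spec
    sp$amplitude <- base_spec$amplitude * amount_map[i]
    sp$orientation_angle <- angle_map[i]
    sp$aligned_fraction <- degree_map[i]
    sp$rng_seed <- base_spec$rng_seed + i
    patterns[[i]] <- simulate_diffraction_pattern(sp)
  }
  structure(list(patterns = patterns, grid_dim = nxy,
                 geometry = sim_geometry(base_spec), base_spec = base_spec),
            class = "diffraction_scan")
}

#' @export
print.diffraction_scan <- function(x, ...) {
  cat(sprintf("diffraction_scan: %d x %d positions, %d x %d px detector\n",
              x$grid_dim[1], x$grid_dim[2],
              x$geometry$detector_px[1], x$geometry$detector_px[2]))
  invisible(x)
}
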