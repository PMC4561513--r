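# Scanning micro-diffraction analysis: detector q-mapping, radial and
# azimuthal integration, equatorial collagen peak fitting, and spatial
# collagen maps.
#
# The radial profile I(q) around the collagen lateral-packing reflection is
# modeled as a Gaussian over a second-order polynomial (or power-law)
# background; the fitted position q_c gives the lateral spacing
# D = 2 pi / q_c. The azimuthal profile I(Phi) over the ring is modeled as
# a constant plus two wrapped Gaussians 180 degrees apart with shared
# amplitude and width; the orientation degree is the ratio A_Phi / A_BKG of
# the area under the peaks (aligned molecules) to the area under the
# constant background (randomly oriented molecules).

#' Detector geometry for diffraction patterns
#'
#' @param wavelength_nm X-ray wavelength, nm (default 0.0976 nm)
#' @param distance_mm sample-detector distance, mm (default 1100 mm)
#' @param pixel_size_mm pixel pitch, mm
#' @param detector_px detector size in pixels `(n, m)`
#' @param beam_center beam center in pixel coordinates `(cx, cy)`; default
#'   is the detector center; must lie on the detector
#' @return object of class `detector_geometry`
#' @export
detector_geometry <- function(wavelength_nm = 0.0976, distance_mm = 1100,
                              pixel_size_mm = 0.05,
                              detector_px = c(2048L, 2048L),
                              beam_center = NULL) {
  check_scalar_positive(wavelength_nm, "wavelength_nm")
  check_scalar_positive(distance_mm, "distance_mm")
  check_scalar_positive(pixel_size_mm, "pixel_size_mm")
  if (!is.numeric(detector_px) || length(detector_px) != 2L ||
      any(detector_px < 1))
    stop_field("detector_px", "must be two positive integers")
  if (is.null(beam_center))
    beam_center <- (detector_px + 1) / 2
  if (!is.numeric(beam_center) || length(beam_center) != 2L ||
      any(beam_center < 1) || any(beam_center > detector_px))
    stop_field("beam_center", "must lie inside the detector")
  structure(list(wavelength_nm = wavelength_nm, distance_mm = distance_mm,
                 pixel_size_mm = pixel_size_mm,
                 detector_px = as.integer(detector_px),
                 beam_center = beam_center),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "detector_geometry: %dx%d px @ %g mm, L = %g mm, lambda = %g nm\n",
    x$detector_px[1], x$detector_px[2], x$pixel_size_mm, x$distance_mm,
    x$wavelength_nm))
  invisible(x)
}

#' Per-pixel scattering vector and azimuth maps
#'
#' For each pixel at radial distance `r` from the beam center,
#' `2 theta = atan(r / L)` and `q = 4 pi sin(theta) / lambda` (1/nm).
#' The azimuth `Phi` is measured counterclockwise from the detector +x
#' (first index) axis, in degrees in `[0, 360)`.
#'
#' @param geom a [detector_geometry()]
#' @return list with matrices `q` (1/nm) and `phi` (degrees)
#' @examples
#' g <- detector_geometry(detector_px = c(64, 64), pixel_size_mm = 1)
#' range(q_map(g)$q)
#' @export
q_map <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  dx <- (seq_len(geom$detector_px[1]) - geom$beam_center[1]) *
    geom$pixel_size_mm
  dy <- (seq_len(geom$detector_px[2]) - geom$beam_center[2]) *
    geom$pixel_size_mm
  r <- sqrt(outer(dx^2, dy^2, `+`))
  theta <- atan(r / geom$distance_mm) / 2
  q <- 4 * pi * sin(theta) / geom$wavelength_nm
  phi <- (outer(dx, dy, function(a, b) atan2(b, a)) * 180 / pi) %% 360
  list(q = q, phi = phi)
}

#' Radial (azimuthally averaged) intensity profile
#'
#' Mean intensity per equal-width q bin. Empty bins are reported with `NA`
#' intensity and excluded from downstream fits. Per-bin pixel counts and
#' raw sums are kept so that binned counts conserve the total pattern
#' counts in the covered region.
#'
#' @param pattern detector image (matrix)
#' @param geom a [detector_geometry()] (default: the pattern's `geometry`
#'   attribute)
#' @param n_bins number of q bins
#' @param q_range q interval to histogram, 1/nm (default: full detector
#'   coverage); must intersect the detector coverage
#' @param maps optional precomputed [q_map()] result for this geometry
#' @return `radial_profile` data frame with columns `q`, `intensity`,
#'   `n_pixels`, `sum`
#' @export
radial_integrate <- function(pattern, geom = attr(pattern, "geometry"),
                             n_bins = 200L, q_range = NULL, maps = NULL) {
  if (is.null(geom)) stop("detector geometry required")
  if (is.null(maps)) maps <- q_map(geom)
  if (!all(dim(pattern) == dim(maps$q)))
    stop("pattern shape does not match detector geometry")
  qv <- as.vector(maps$q)
  if (is.null(q_range)) q_range <- range(qv)
  check_range(q_range, "q_range")
  if (q_range[1] >= max(qv) || q_range[2] <= min(qv))
    stop("q_range lies outside the detector coverage")
  edges <- seq(q_range[1], q_range[2], length.out = n_bins + 1)
  idx <- findInterval(qv, edges, rightmost.closed = TRUE)
  ok <- idx >= 1L & idx <= n_bins
  counts <- tabulate(idx[ok], nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(as.vector(pattern)[ok], idx[ok])
  sums[as.integer(rownames(agg))] <- agg[, 1]
  structure(data.frame(q = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                       intensity = ifelse(counts > 0, sums / pmax(counts, 1),
                                          NA_real_),
                       n_pixels = counts, sum = sums),
            class = c("radial_profile", "data.frame"),
            q_range = q_range)
}

#' Azimuthal intensity profile over a q window
#'
#' Mean intensity per azimuth bin over the pixels whose q falls inside
#' `q_window` (by default a window around the collagen equatorial ring at
#' 5.6 1/nm).
#'
#' @param pattern detector image (matrix)
#' @param geom a [detector_geometry()] (default: pattern attribute)
#' @param q_window q interval selecting the ring, 1/nm
#' @param n_bins number of azimuth bins over the full circle
#' @param maps optional precomputed [q_map()]
#' @return `azimuthal_profile` data frame with columns `phi`, `intensity`,
#'   `n_pixels`, `sum`
#' @export
azimuthal_integrate <- function(pattern, geom = attr(pattern, "geometry"),
                                q_window = c(4.6, 6.6), n_bins = 72L,
                                maps = NULL) {
  if (is.null(geom)) stop("detector geometry required")
  if (is.null(maps)) maps <- q_map(geom)
  if (!all(dim(pattern) == dim(maps$q)))
    stop("pattern shape does not match detector geometry")
  check_range(q_window, "q_window")
  sel <- maps$q >= q_window[1] & maps$q <= q_window[2]
  if (!any(sel))
    stop("q_window selects no detector pixels (empty window)")
  width <- 360 / n_bins
  idx <- pmin(floor(maps$phi[sel] / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(pattern[sel], idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  structure(data.frame(phi = (seq_len(n_bins) - 0.5) * width,
                       intensity = ifelse(counts > 0, sums / pmax(counts, 1),
                                          NA_real_),
                       n_pixels = counts, sum = sums),
            class = c("azimuthal_profile", "data.frame"),
            q_window = q_window)
}

flagged_peak_fit <- function(flag, background_model, goodness = NA_real_) {
  structure(list(q_c = NA_real_, sigma_q = NA_real_, amplitude = 0,
                 peak_area = 0, background_model = background_model,
                 background_coeffs = NULL, lateral_spacing = NA_real_,
                 goodness = goodness, converged = FALSE, flag = flag),
            class = "collagen_peak_fit")
}

#' Fit the equatorial collagen peak in a radial profile
#'
#' Least-squares fit of a Gaussian plus background over a q window:
#' `I(q) = A exp(-(q - q_c)^2 / (2 sigma^2)) + B(q)` with `B` either a
#' second-order polynomial (default) or a power law `a q^-k`. The peak
#' position is initialized at the argmax of a median-smoothed window, the
#' width at one sixth of the window, and the background by fitting `B`
#' alone to the outer quarter of the window bins. A window without an
#' interior local maximum, or a vanishing fitted amplitude, yields a
#' flagged no-peak result (not an error); non-convergence is likewise
#' flagged. `lateral_spacing` is `2 pi / q_c` (nm).
#'
#' @param profile a `radial_profile`
#' @param window q window to fit, 1/nm; must contain at least 8 bins
#' @param background `"poly2"` or `"powerlaw"`
#' @return object of class `collagen_peak_fit`: `q_c`, `sigma_q`,
#'   `amplitude`, `peak_area` (`A sigma sqrt(2 pi)`), `background_coeffs`,
#'   `lateral_spacing`, `goodness` (residual RMS), `converged`, `flag`
#' @export
fit_collagen_peak <- function(profile, window = c(4.6, 6.6),
                              background = c("poly2", "powerlaw")) {
  background <- match.arg(background)
  stopifnot(inherits(profile, "radial_profile"))
  check_range(window, "window")
  sel <- profile$q >= window[1] & profile$q <= window[2] &
    !is.na(profile$intensity)
  if (sum(sel) < 8)
    stop("fit window must contain at least 8 non-empty bins")
  q <- profile$q[sel]
  I <- profile$intensity[sel]
  nw <- length(q)

  smoothed <- stats::runmed(I, k = 3)
  imax <- which.max(smoothed)
  no_local_max <- imax <= 1L || imax >= nw

  n_edge <- max(2L, ceiling(0.125 * nw))
  edge <- c(seq_len(n_edge), seq.int(nw - n_edge + 1L, nw))
  qe <- q[edge]; Ie <- I[edge]
  if (background == "poly2") {
    bgfit <- lm(Ie ~ qe + I(qe^2))
    bg0 <- unname(coef(bgfit))
    bg_at <- function(x) bg0[1] + bg0[2] * x + bg0[3] * x^2
    start <- list(A = max(I[imax] - bg_at(q[imax]), 1e-6 * max(abs(I))),
                  qc = q[imax], s = diff(window) / 6,
                  c0 = bg0[1], c1 = bg0[2], c2 = bg0[3])
    formula <- I ~ A * exp(-(q - qc)^2 / (2 * s^2)) + c0 + c1 * q + c2 * q^2
    lower <- c(A = 0, qc = window[1], s = 1e-4,
               c0 = -Inf, c1 = -Inf, c2 = -Inf)
    upper <- c(A = Inf, qc = window[2], s = diff(window), c0 = Inf,
               c1 = Inf, c2 = Inf)
  } else {
    Ipos <- pmax(Ie, 1e-9)
    llfit <- lm(log(Ipos) ~ log(qe))
    a0 <- exp(unname(coef(llfit))[1])
    k0 <- -unname(coef(llfit))[2]
    bg_at <- function(x) a0 * x^(-k0)
    start <- list(A = max(I[imax] - bg_at(q[imax]), 1e-6 * max(abs(I))),
                  qc = q[imax], s = diff(window) / 6, a = a0, k = k0)
    formula <- I ~ A * exp(-(q - qc)^2 / (2 * s^2)) + a * q^(-k)
    lower <- c(A = 0, qc = window[1], s = 1e-4, a = 0, k = -Inf)
    upper <- c(A = Inf, qc = window[2], s = diff(window), a = Inf, k = Inf)
  }
  if (no_local_max)
    return(flagged_peak_fit("no_peak", background, goodness = sd(I)))

  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data.frame(q = q, I = I),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(flagged_peak_fit("no_convergence", background))
  cf <- coef(fit)
  goodness <- sqrt(mean(residuals(fit)^2))
  flag <- if (cf[["A"]] <= 1e-6 * max(abs(I))) "no_peak" else "ok"
  bg_coeffs <- if (background == "poly2") {
    c(c0 = cf[["c0"]], c1 = cf[["c1"]], c2 = cf[["c2"]])
  } else {
    c(a = cf[["a"]], k = cf[["k"]])
  }
  structure(list(q_c = cf[["qc"]], sigma_q = cf[["s"]],
                 amplitude = cf[["A"]],
                 peak_area = cf[["A"]] * cf[["s"]] * sqrt(2 * pi),
                 background_model = background,
                 background_coeffs = bg_coeffs,
                 lateral_spacing = 2 * pi / cf[["qc"]],
                 goodness = goodness, converged = TRUE, flag = flag),
            class = "collagen_peak_fit")
}

#' @export
print.collagen_peak_fit <- function(x, ...) {
  if (x$flag != "ok") {
    cat(sprintf("collagen_peak_fit: flagged '%s'\n", x$flag))
  } else {
    cat(sprintf(
      "collagen_peak_fit: q_c = %.4g 1/nm (D = %.4g nm), sigma = %.3g, area = %.4g\n",
      x$q_c, x$lateral_spacing, x$sigma_q, x$peak_area))
  }
  invisible(x)
}

#' Fit the azimuthal orientation distribution
#'
#' Least-squares fit of `I(Phi) = c + A [G(Phi - Phi0) + G(Phi - Phi0 -
#' 180)]` with wrapped Gaussians of shared amplitude and width (the
#' symmetry of an equatorial reflection). The aligned-material area is
#' `A_Phi = 2 A sigma sqrt(2 pi)`, the random background area is
#' `A_BKG = c * 360`, and the orientation degree is their ratio. A flat
#' profile returns degree 0 with flag `"flat"`; a negative fitted
#' background is flagged.
#'
#' @param profile an `azimuthal_profile` covering the full circle
#' @return object of class `orientation_fit`: `orientation_angle` (degrees
#'   mod 180), `sigma_phi`, `amplitude`, `background`, `a_phi`, `a_bkg`,
#'   `degree`, `goodness`, `converged`, `flag`
#' @export
fit_orientation <- function(profile) {
  stopifnot(inherits(profile, "azimuthal_profile"))
  ok <- !is.na(profile$intensity)
  phi <- profile$phi[ok]
  I <- profile$intensity[ok]
  if (diff(range(profile$phi)) < 300)
    stop("azimuthal profile must cover the full circle")
  base <- list(background = mean(I), a_bkg = mean(I) * 360)
  if (diff(range(I)) <= 1e-9 * (abs(mean(I)) + 1e-12)) {
    return(structure(c(list(orientation_angle = NA_real_,
                            sigma_phi = NA_real_, amplitude = 0,
                            a_phi = 0, degree = 0, goodness = 0,
                            converged = TRUE, flag = "flat"), base),
                     class = "orientation_fit"))
  }
  start <- list(A = diff(range(I)), phi0 = phi[which.max(I)] %% 180,
                s = 20, c0 = min(I))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ c0 + A * wrapped_pair(phi - phi0, s),
      data = data.frame(phi = phi, I = I), start = start,
      lower = c(A = 0, phi0 = -360, s = 1, c0 = -Inf),
      upper = c(A = Inf, phi0 = 360, s = 90, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(c(list(orientation_angle = NA_real_,
                            sigma_phi = NA_real_, amplitude = 0,
                            a_phi = 0, degree = NA_real_,
                            goodness = NA_real_, converged = FALSE,
                            flag = "no_convergence"), base),
                     class = "orientation_fit"))
  }
  cf <- coef(fit)
  a_phi <- 2 * cf[["A"]] * cf[["s"]] * sqrt(2 * pi)
  a_bkg <- cf[["c0"]] * 360
  flag <- if (cf[["c0"]] < 0) "negative_background" else "ok"
  structure(list(orientation_angle = cf[["phi0"]] %% 180,
                 sigma_phi = cf[["s"]], amplitude = cf[["A"]],
                 background = cf[["c0"]], a_phi = a_phi, a_bkg = a_bkg,
                 degree = a_phi / a_bkg,
                 goodness = sqrt(mean(residuals(fit)^2)),
                 converged = TRUE, flag = flag),
            class = "orientation_fit")
}

#' @export
print.orientation_fit <- function(x, ...) {
  if (x$flag %in% c("ok", "flat")) {
    cat(sprintf(
      "orientation_fit: angle = %s deg, degree A_Phi/A_BKG = %.3g (%s)\n",
      if (is.na(x$orientation_angle)) "NA"
      else sprintf("%.2f", x$orientation_angle),
      x$degree, x$flag))
  } else {
    cat(sprintf("orientation_fit: flagged '%s'\n", x$flag))
  }
  invisible(x)
}

#' Spatial collagen map from a scan grid of patterns
#'
#' Runs the radial + azimuthal integration and both fits at every scan
#' position and assembles amount (collagen peak area), orientation angle
#' and orientation degree rasters. Positions whose peak fit is flagged
#' (including zero-collagen positions) are masked out via the `ok` raster.
#'
#' @param scan a `diffraction_scan` from [simulate_scan_grid()], or a plain
#'   list of pattern matrices with `grid_dim`
#' @param geom a [detector_geometry()] (default: taken from the scan)
#' @param q_window ring window for azimuthal integration and peak fit
#' @param background background model for the peak fit
#' @param n_radial_bins,n_phi_bins integration binning
#' @return object of class `collagen_map` with rasters `amount`, `angle`,
#'   `degree`, `ok` and a long-format `table` (one row per position) usable
#'   as a vector-plot export (arrow direction = angle, length = degree,
#'   background intensity = amount)
#' @export
build_collagen_map <- function(scan, geom = NULL, q_window = c(4.6, 6.6),
                               background = c("poly2", "powerlaw"),
                               n_radial_bins = 150L, n_phi_bins = 72L) {
  background <- match.arg(background)
  if (inherits(scan, "diffraction_scan")) {
    patterns <- scan$patterns
    grid_dim <- scan$grid_dim
    if (is.null(geom)) geom <- scan$geometry
  } else {
    patterns <- scan$patterns
    grid_dim <- scan$grid_dim
  }
  if (is.null(geom)) stop("detector geometry required")
  if (length(patterns) == 0) stop("scan grid must be non-empty")
  maps <- q_map(geom)
  q_lo <- max(min(maps$q), 0.5)
  amount <- angle <- degree <- matrix(NA_real_, grid_dim[1], grid_dim[2])
  okm <- matrix(FALSE, grid_dim[1], grid_dim[2])
  rows <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    rp <- radial_integrate(patterns[[i]], geom, n_bins = n_radial_bins,
                           q_range = c(q_lo, max(maps$q)), maps = maps)
    pk <- fit_collagen_peak(rp, window = q_window, background = background)
    ap <- azimuthal_integrate(patterns[[i]], geom, q_window = q_window,
                              n_bins = n_phi_bins, maps = maps)
    orf <- fit_orientation(ap)
    pos_ok <- pk$flag == "ok" && orf$flag %in% c("ok", "flat")
    okm[i] <- pos_ok
    if (pos_ok) {
      amount[i] <- pk$peak_area
      angle[i] <- orf$orientation_angle
      degree[i] <- orf$degree
    }
    ij <- arrayInd(i, grid_dim)
    rows[[i]] <- data.frame(ix = ij[1], iy = ij[2],
                            amount = if (pos_ok) pk$peak_area else NA_real_,
                            angle_deg = if (pos_ok) orf$orientation_angle
                            else NA_real_,
                            degree = if (pos_ok) orf$degree else NA_real_,
                            ok = pos_ok,
                            peak_flag = pk$flag, orient_flag = orf$flag)
  }
  structure(list(amount = amount, angle = angle, degree = degree, ok = okm,
                 table = do.call(rbind, rows), q_window = q_window,
                 background = background),
            class = "collagen_map")
}

#' @export
print.collagen_map <- function(x, ...) {
  cat(sprintf("collagen_map: %d x %d positions (%d fitted, %d masked)\n",
              nrow(x$amount), ncol(x$amount), sum(x$ok), sum(!x$ok)))
  invisible(x)
}

#' Vector plot of a collagen map
#'
#' Amount raster as background image with orientation arrows whose
#' direction is the fitted angle and length is proportional to the
#' orientation degree.
#'
#' @param x a `collagen_map`
#' @param arrow_scale arrow half-length per unit degree, in grid units
#' @param ... passed to [graphics::image()]
#' @export
plot.collagen_map <- function(x, arrow_scale = 0.4, ...) {
  amount <- x$amount
  amount[!x$ok] <- 0
  graphics::image(seq_len(nrow(amount)), seq_len(ncol(amount)), amount,
                  xlab = "scan x", ylab = "scan y", ...)
  idx <- which(x$ok & is.finite(x$degree), arr.ind = TRUE)
  if (nrow(idx)) {
    ang <- x$angle[idx] * pi / 180
    len <- arrow_scale * x$degree[idx] / max(x$degree[idx], na.rm = TRUE)
    graphics::arrows(idx[, 1] - len * cos(ang), idx[, 2] - len * sin(ang),
                     idx[, 1] + len * cos(ang), idx[, 2] + len * sin(ang),
                     length = 0.03, code = 3)
  }
  invisible(x)
}
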