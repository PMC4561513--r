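# Parallel-beam tomography: radon transform of a slice and ramp-filtered
# back projection. The detector grid coincides with the slice grid; line
# integrals carry physical length units (values x pixel size).

#' Parallel-beam radon transform of a 2D slice
#'
#' Line integrals along parallel rays at each angle, computed by bilinear
#' sampling on the rotated grid and scaled by the pixel size so that the
#' projection of a binary object is its chord length in physical units.
#'
#' @param slice square numeric matrix
#' @param angles projection angles in degrees
#' @param pixel_size pixel spacing (length units, default 1)
#' @return `n x length(angles)` sinogram with attributes `angles` and
#'   `pixel_size`
#' @export
radon_project <- function(slice, angles, pixel_size = 1) {
  if (!is.matrix(slice) || nrow(slice) != ncol(slice))
    stop("slice must be a square matrix")
  if (length(angles) == 0) stop("angle list must not be empty")
  if (!all(is.finite(slice))) stop("slice must be finite")
  sino <- .radon_cpp(slice, angles * pi / 180) * pixel_size
  attr(sino, "angles") <- angles
  attr(sino, "pixel_size") <- pixel_size
  sino
}

#' Filtered back projection of a parallel-beam sinogram
#'
#' Ramp-filtered (optionally Hann-apodized) back projection with linear
#' interpolation. Angles must cover at least 180 degrees; acquisitions over
#' more than 180 degrees (e.g. a full turn) are folded onto `[0, 180)` by
#' flipping the detector axis of the extra projections.
#'
#' @param sinogram `n_det x n_angles` matrix (e.g. from [radon_project()])
#' @param angles projection angles in degrees (default: the sinogram's
#'   `angles` attribute)
#' @param filter_name `"ramp"` or `"hann"`
#' @param pixel_size detector pixel spacing (default: sinogram attribute,
#'   else 1)
#' @return reconstructed `n_det x n_det` slice
#' @export
fbp_reconstruct <- function(sinogram, angles = NULL,
                            filter_name = c("ramp", "hann"),
                            pixel_size = NULL) {
  filter_name <- match.arg(filter_name)
  if (is.null(angles)) angles <- attr(sinogram, "angles")
  if (is.null(pixel_size)) pixel_size <- attr(sinogram, "pixel_size")
  if (is.null(pixel_size)) pixel_size <- 1
  if (is.null(angles) || length(angles) != ncol(sinogram))
    stop("angles must match the sinogram columns")
  if (length(angles) < 2) stop("need at least 2 projection angles")
  step <- median(diff(sort(angles)))
  span <- max(angles) - min(angles) + step
  if (span < 180 - 1e-6)
    stop(sprintf("angular coverage %.1f deg is insufficient (need >= 180)",
                 span))
  # fold angles beyond [0, 180) onto the half turn, flipping the detector
  ang <- angles %% 360
  flip <- ang >= 180
  ang[flip] <- ang[flip] - 180
  sino <- sinogram
  if (any(flip)) sino[, flip] <- sino[nrow(sino):1, flip]

  # zero-pad the detector axis before the ramp filter: the filter is a
  # convolution with slowly decaying tails, and circular wrap-around would
  # otherwise bias the reconstruction (cupping)
  nd <- nrow(sino)
  npad <- stats::nextn(2 * nd, c(2L, 3L, 5L))
  sp <- rbind(sino, matrix(0, npad - nd, ncol(sino)))
  f <- fft_freq(npad, pixel_size)
  ramp <- abs(f)
  if (filter_name == "hann") {
    fmax <- max(abs(f))
    ramp <- ramp * 0.5 * (1 + cos(pi * f / fmax))
  }
  filt <- Re(mvfft(mvfft(sp) * ramp, inverse = TRUE)) / npad
  filt <- filt[seq_len(nd), , drop = FALSE]
  recon <- .backproject_cpp(filt, ang * pi / 180, nd)
  recon * pi / length(ang)
}
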