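# shared validation and numeric helpers

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_scalar_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_field(field, "must be a single positive finite number")
  invisible(x)
}

check_range <- function(x, field) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] >= x[2])
    stop_field(field, "must be an increasing pair (lo, hi)")
  invisible(x)
}

#' Unnormalized FFT sample frequencies
#'
#' Frequencies in cycles per physical unit for an `n`-point grid with sample
#' spacing `d`, in standard FFT order (DC first, negative frequencies in the
#' upper half).
#' @param n number of samples
#' @param d sample spacing (physical units)
#' @return numeric vector of length `n`
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# composite FFT-friendly padded size (>= 1.5 n, mixed radix 2/3/5)
pad_size <- function(n) stats::nextn(ceiling(1.5 * n), c(2L, 3L, 5L))

# reflective (mirror, no edge repeat) padding of a matrix to nr x nc,
# split as evenly as possible; inverse is crop_matrix
pad_reflect <- function(x, nr, nc) {
  reflect_idx <- function(n, pad_lo, pad_hi) {
    if (pad_lo >= n || pad_hi >= n)
      stop("padding exceeds image size; input too small to pad reflectively")
    c(rev(seq_len(pad_lo) + 1L), seq_len(n), n - seq_len(pad_hi))
  }
  plo_r <- floor((nr - nrow(x)) / 2); phi_r <- nr - nrow(x) - plo_r
  plo_c <- floor((nc - ncol(x)) / 2); phi_c <- nc - ncol(x) - plo_c
  x[reflect_idx(nrow(x), plo_r, phi_r), reflect_idx(ncol(x), plo_c, phi_c),
    drop = FALSE]
}

crop_matrix <- function(x, nr, nc) {
  plo_r <- floor((nrow(x) - nr) / 2)
  plo_c <- floor((ncol(x) - nc) / 2)
  x[plo_r + seq_len(nr), plo_c + seq_len(nc), drop = FALSE]
}

# shift a 3D array by one voxel along `axis` (+1/-1), zero-filling
shift_array <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (by == 1L) {
    idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1)
  } else {
    idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# radius-1 binary erosion/dilation with the 6-connected cross element;
# EBImage morphology is frame-wise 2D, so true 3D opening lives here
erode6 <- function(a) {
  out <- a
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift_array(a, ax, by)
  out
}

dilate6 <- function(a) {
  out <- a
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | shift_array(a, ax, by)
  out
}

open3d <- function(a) dilate6(erode6(a))

# wrap angular difference into [-180, 180)
wrap180 <- function(x) ((x + 180) %% 360) - 180

# wrap into [-90, 90) (differences between axial, 180-degree-periodic angles)
wrap90 <- function(x) ((x + 90) %% 180) - 90

axis_index <- function(axis) {
  if (is.character(axis)) {
    i <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(i)) stop("axis must be one of 'x', 'y', 'z'", call. = FALSE)
    return(i)
  }
  if (is.numeric(axis) && axis %in% 1:3) return(as.integer(axis))
  stop("axis must be one of 'x', 'y', 'z'", call. = FALSE)
}

# move the chosen axis to the third slot so slices are a[, , k]
axis_last <- function(a, axis) {
  i <- axis_index(axis)
  perm <- switch(i, c(2L, 3L, 1L), c(1L, 3L, 2L), c(1L, 2L, 3L))
  if (i == 3L) a else aperm(a, perm)
}
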