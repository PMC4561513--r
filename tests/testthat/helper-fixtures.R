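# programmatic fixtures shared across tests

# voxel centers at (i - 0.5) * voxel_size, matching the phantom convention
grid_coords <- function(dims, voxel_size = 1) {
  lapply(dims, function(n) (seq_len(n) - 0.5) * voxel_size)
}

# solid cylinder along the z axis spanning the full volume
make_tube_mask <- function(dims = c(24L, 24L, 24L), radius = 4,
                           center = NULL, voxel_size = 1) {
  co <- grid_coords(dims, voxel_size)
  if (is.null(center)) center <- (dims[1:2] / 2) * voxel_size
  disk <- outer((co[[1]] - center[1])^2, (co[[2]] - center[2])^2, `+`) <=
    radius^2
  array(rep(disk, dims[3]), dims)
}

# mark voxels within `radius` of the segment p0-p1 (coordinates in voxels)
stamp_segment <- function(mask, p0, p1, radius, voxel_size = 1) {
  dims <- dim(mask)
  co <- grid_coords(dims, voxel_size)
  g <- expand.grid(x = co[[1]], y = co[[2]], z = co[[3]])
  d <- p1 - p0
  len2 <- sum(d^2)
  tt <- ((g$x - p0[1]) * d[1] + (g$y - p0[2]) * d[2] +
           (g$z - p0[3]) * d[3]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  dist2 <- (g$x - (p0[1] + tt * d[1]))^2 + (g$y - (p0[2] + tt * d[2]))^2 +
    (g$z - (p0[3] + tt * d[3]))^2
  mask | array(dist2 <= radius^2, dims)
}

# Y-shaped tube: stem along z splitting into two oblique children
make_y_mask <- function(dims = c(40L, 40L, 40L), radius = 3) {
  m <- array(FALSE, dims)
  mid <- dims[1] / 2
  m <- stamp_segment(m, c(mid, mid, 2), c(mid, mid, 20), radius)
  m <- stamp_segment(m, c(mid, mid, 20), c(mid - 11, mid, 37), radius)
  stamp_segment(m, c(mid, mid, 20), c(mid + 11, mid, 37), radius)
}

# solid torus in the central xy-plane
make_ring_mask <- function(dims = c(40L, 40L, 16L), ring_radius = 12,
                           tube_radius = 3) {
  co <- grid_coords(dims)
  ctr <- dims / 2
  g <- expand.grid(x = co[[1]], y = co[[2]], z = co[[3]])
  rho <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2)
  array((rho - ring_radius)^2 + (g$z - ctr[3])^2 <= tube_radius^2, dims)
}

# smooth strictly positive band-limited thickness map on a periodic domain
band_limited_map <- function(n, seed, cutoff = 0.06, height = 20) {
  withr::with_seed(seed, {
    w <- matrix(rnorm(n * n), n)
    f <- microvasq:::fft_freq(n)
    H <- exp(-outer(f^2, f^2, `+`) / (2 * cutoff^2))
    x <- Re(fft(fft(w) * H, inverse = TRUE)) / n^2
    (x - min(x)) / diff(range(x)) * height
  })
}

# phantom spec for perfectly straight, axis-aligned, unbranched vessels
straight_phantom_spec <- function(n = 48L, n_trees = 1L, seed = 3L, ...) {
  phantom_spec(shape_voxels = rep(n, 3), n_trees = n_trees,
               branch_probability = 0, direction_jitter = 0,
               scaffold_volume_fraction = 0, rng_seed = seed, ...)
}

# hand-built vessel tree truth: one parent of diameter d_parent splitting
# at depth z_split into two children of diameter d_child (all along +z)
make_y_truth <- function(d_parent = 18, d_child = 12, z_split = 15,
                         z_max = 30, extent = c(30, 30, 30)) {
  zs1 <- seq(0, z_split, by = 1)
  zs2 <- seq(z_split, z_max, by = 1)
  pts <- rbind(
    data.frame(tree = 1L, segment = 1L, parent = NA_integer_,
               point = seq_along(zs1), x = 15, y = 15, z = zs1,
               radius = d_parent / 2),
    data.frame(tree = 1L, segment = 2L, parent = 1L,
               point = seq_along(zs2), x = 15 - seq_along(zs2) * 0.3,
               y = 15, z = zs2, radius = d_child / 2),
    data.frame(tree = 1L, segment = 3L, parent = 1L,
               point = seq_along(zs2), x = 15 + seq_along(zs2) * 0.3,
               y = 15, z = zs2, radius = d_child / 2))
  structure(list(points = pts, extent_um = extent, voxel_size = 1,
                 entry_face = "z-"),
            class = "vessel_tree_truth")
}
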