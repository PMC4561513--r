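# Synthetic scaffold + vessel-tree phantoms with analytic ground truth.
#
# The phantom emulates a porous ceramic scaffold whose pore space is crossed
# by tubular branching vessel trees of 10-20 um diameter at 0.64 um voxels.
# Trees grow as a biased random walk from an entry face with Poisson
# branching per unit length; every centerline point carries an analytic
# radius, so depth-resolved counts have an exact oracle.

#' Specification of a scaffold + vessel phantom
#'
#' @param shape_voxels integer triple, volume shape in voxels (all >= 16)
#' @param voxel_size isotropic voxel size, micrometers
#' @param n_trees number of vessel trees entering the volume
#' @param root_entry_face entry face, one of `"z-"`, `"z+"`, `"x-"`, `"x+"`,
#'   `"y-"`, `"y+"`; trees grow along the inward normal
#' @param branch_probability probability of a branch event per micrometer of
#'   centerline
#' @param diameter_range vessel diameter range `(d_min, d_max)`, micrometers;
#'   `d_min` must exceed twice the voxel size so vessels stay resolvable
#' @param taper_factor multiplicative radius reduction applied to both
#'   children at a branch point (clamped so diameters never drop below
#'   `d_min`)
#' @param pore_radius_range scaffold pore radius range, micrometers
#' @param scaffold_volume_fraction target solid fraction of the scaffold
#'   matrix, in `[0, 1)`
#' @param direction_jitter standard deviation of the per-step random
#'   deflection of the growth direction (0 gives perfectly straight,
#'   axis-aligned vessels)
#' @param axis_bias persistent pull of the growth direction toward the entry
#'   normal, per step
#' @param rng_seed integer seed; the phantom is bit-reproducible given the
#'   full spec
#' @return an object of class `phantom_spec`
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape_voxels = c(256L, 256L, 256L),
                         voxel_size = 0.64,
                         n_trees = 3L,
                         root_entry_face = "z-",
                         branch_probability = 0.015,
                         diameter_range = c(10, 20),
                         taper_factor = 0.85,
                         pore_radius_range = c(15, 40),
                         scaffold_volume_fraction = 0.35,
                         direction_jitter = 0.12,
                         axis_bias = 0.15,
                         rng_seed = 1L) {
  if (!is.numeric(shape_voxels) || length(shape_voxels) != 3L ||
      any(shape_voxels < 16))
    stop_field("shape_voxels", "must be three integers all >= 16")
  check_scalar_positive(voxel_size, "voxel_size")
  if (!is.numeric(n_trees) || length(n_trees) != 1L || n_trees < 0)
    stop_field("n_trees", "must be a single non-negative integer")
  faces <- c("x-", "x+", "y-", "y+", "z-", "z+")
  if (!is.character(root_entry_face) || !(root_entry_face %in% faces))
    stop_field("root_entry_face", "must be one of x-, x+, y-, y+, z-, z+")
  if (!is.numeric(branch_probability) || branch_probability < 0)
    stop_field("branch_probability", "must be non-negative")
  check_range(diameter_range, "diameter_range")
  if (diameter_range[1] <= 2 * voxel_size)
    stop_field("diameter_range",
               "d_min must exceed 2 x voxel_size for vessels to be resolvable")
  if (!is.numeric(taper_factor) || taper_factor <= 0 || taper_factor > 1)
    stop_field("taper_factor", "must be in (0, 1]")
  check_range(pore_radius_range, "pore_radius_range")
  if (!is.numeric(scaffold_volume_fraction) ||
      scaffold_volume_fraction < 0 || scaffold_volume_fraction >= 1)
    stop_field("scaffold_volume_fraction", "must be in [0, 1)")
  if (!is.numeric(direction_jitter) || direction_jitter < 0)
    stop_field("direction_jitter", "must be non-negative")
  structure(list(
    shape_voxels = as.integer(shape_voxels), voxel_size = voxel_size,
    n_trees = as.integer(n_trees), root_entry_face = root_entry_face,
    branch_probability = branch_probability,
    diameter_range = diameter_range, taper_factor = taper_factor,
    pore_radius_range = pore_radius_range,
    scaffold_volume_fraction = scaffold_volume_fraction,
    direction_jitter = direction_jitter, axis_bias = axis_bias,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %s voxels @ %.3g um, %d tree(s), diameters %g-%g um\n",
    paste(x$shape_voxels, collapse = "x"), x$voxel_size, x$n_trees,
    x$diameter_range[1], x$diameter_range[2]))
  invisible(x)
}

# default refractive-index properties per material label at 24 keV scale;
# the vessel compartment mimics a radiopaque-perfused lumen
default_materials <- function() {
  list(soft     = list(delta = 5e-8, beta = 5e-11),
       scaffold = list(delta = 4e-7, beta = 1e-9),
       vessel   = list(delta = 1e-7, beta = 5e-10))
}

labeled_volume <- function(labels, voxel_size, materials = default_materials()) {
  stopifnot(length(dim(labels)) == 3L)
  for (m in names(materials)) {
    if (materials[[m]]$delta <= 0 || materials[[m]]$beta <= 0)
      stop_field(m, "material delta and beta must be positive")
  }
  structure(list(labels = labels, voxel_size = voxel_size,
                 materials = materials),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "labeled_volume: %dx%dx%d @ %.3g um/voxel (vessel fraction %.3g)\n",
    d[1], d[2], d[3], x$voxel_size, mean(x$labels == 2L)))
  invisible(x)
}

rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma_cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_perpendicular <- function(v) {
  u <- rnorm(3)
  u <- u - sum(u * v) * v / sum(v^2)
  n <- sqrt(sum(u^2))
  if (n < 1e-9) return(random_perpendicular(v))
  u / n
}

entry_axis <- function(face) {
  ax <- axis_index(substr(face, 1, 1))
  sgn <- if (substr(face, 2, 2) == "-") 1 else -1
  dir <- c(0, 0, 0)
  dir[ax] <- sgn
  list(axis = ax, dir = dir, from_low = sgn == 1)
}

# grow all trees; returns per-point data.frame in micrometer coordinates
grow_trees <- function(spec) {
  extent <- spec$shape_voxels * spec$voxel_size
  ent <- entry_axis(spec$root_entry_face)
  step <- spec$voxel_size
  d_min <- spec$diameter_range[1]
  d_max <- spec$diameter_range[2]
  lateral <- setdiff(1:3, ent$axis)

  # root radii first, so entry margins and separations can use the actual
  # tube sizes rather than the worst case
  root_radii <- runif(spec$n_trees, (d_min + d_max) / 4, d_max / 2)
  margins <- root_radii + 2 * step
  if (spec$n_trees > 0 && any(extent[lateral] <= 2 * max(margins)))
    stop(sprintf(
      "volume too small for vessel entry: lateral extent must exceed %.3g um",
      2 * max(margins)))

  # entry points on the face, pairwise separated so tubes stay distinct
  entries <- matrix(0, nrow = 0, ncol = 2)
  tries <- 0
  while (nrow(entries) < spec$n_trees) {
    k <- nrow(entries) + 1L
    cand <- c(runif(1, margins[k], extent[lateral[1]] - margins[k]),
              runif(1, margins[k], extent[lateral[2]] - margins[k]))
    sep_needed <- root_radii[seq_len(k - 1)] + root_radii[k] + 2 * step
    if (k == 1 ||
        all(sqrt(rowSums(sweep(entries, 2, cand)^2)) > sep_needed)) {
      entries <- rbind(entries, cand)
    }
    tries <- tries + 1
    if (tries > 20000)
      stop("could not place tree entry points; volume too small for n_trees")
  }

  rows <- list()
  seg_counter <- 0L
  for (tree in seq_len(spec$n_trees)) {
    pos0 <- numeric(3)
    pos0[lateral] <- entries[tree, ]
    pos0[ent$axis] <- if (ent$from_low) 0 else extent[ent$axis]
    queue <- list(list(pos = pos0, dir = ent$dir, radius = root_radii[tree],
                       parent = NA_integer_))
    while (length(queue) > 0 && seg_counter < 200L) {
      st <- queue[[1]]
      queue <- queue[-1]
      seg_counter <- seg_counter + 1L
      seg_id <- seg_counter
      pos <- st$pos; dir <- st$dir
      pts <- list(pos)
      repeat {
        nxt <- pos + dir * step
        if (any(nxt < 0) || any(nxt > extent)) {
          # clamp the final point onto the exit boundary so vessels span
          # the full volume (and slice counts agree with the voxel mask)
          tt <- suppressWarnings(min(
            ifelse(dir > 0, (extent - pos) / (dir * step), Inf),
            ifelse(dir < 0, -pos / (dir * step), Inf)))
          if (is.finite(tt) && tt > 1e-9) {
            pts[[length(pts) + 1L]] <- pos + dir * step * min(tt, 1)
          }
          break
        }
        pos <- nxt
        pts[[length(pts) + 1L]] <- pos
        # branch as a Poisson process per unit centerline length
        if (runif(1) < spec$branch_probability * step) {
          child_r <- max(st$radius * spec$taper_factor, d_min / 2)
          for (k in 1:2) {
            ang <- runif(1, pi / 12, pi / 3) # deflection <= 60 degrees
            cdir <- rotate_about(dir, random_perpendicular(dir), ang)
            queue[[length(queue) + 1L]] <-
              list(pos = pos, dir = cdir, radius = child_r, parent = seg_id)
          }
          break
        }
        if (spec$direction_jitter > 0) {
          dir <- dir + spec$direction_jitter * rnorm(3)
          dir <- dir + spec$axis_bias * ent$dir
          dir <- dir / sqrt(sum(dir^2))
        }
      }
      p <- do.call(rbind, pts)
      rows[[length(rows) + 1L]] <- data.frame(
        tree = tree, segment = seg_id, parent = st$parent,
        point = seq_len(nrow(p)),
        x = p[, 1], y = p[, 2], z = p[, 3], radius = st$radius)
    }
  }
  if (length(rows) == 0)
    return(data.frame(tree = integer(), segment = integer(),
                      parent = integer(), point = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      radius = numeric()))
  do.call(rbind, rows)
}

# stamp a sphere of physical radius r (um) centered at p (um) into labels
stamp_sphere <- function(labels, p, r, vs, value) {
  d <- dim(labels)
  lo <- pmax(1L, floor((p - r) / vs + 0.5))
  hi <- pmin(d, ceiling((p + r) / vs + 0.5))
  if (any(lo > hi)) return(labels)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- (ix - 0.5) * vs - p[1]
  cy <- (iy - 0.5) * vs - p[2]
  cz <- (iz - 0.5) * vs - p[3]
  d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  sub <- labels[ix, iy, iz, drop = FALSE]
  sub[d2 <= r^2] <- value
  labels[ix, iy, iz] <- sub
  labels
}

#' Generate a labeled scaffold + vessel phantom
#'
#' Builds a voxel volume with labels 0 (soft tissue / pore space),
#' 1 (scaffold matrix), 2 (vessel lumen) together with the exact vessel
#' centerline truth. The scaffold is a solid matrix minus overlapping
#' spherical pores carved until the target solid fraction is reached;
#' vessel voxels are all voxels within the local radius of some centerline
#' point. Output is bit-reproducible given `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()]
#' @return a list with elements `volume` (class `labeled_volume`) and
#'   `truth` (class `vessel_tree_truth`)
#' @examples
#' ph <- generate_phantom(phantom_spec(shape_voxels = c(48, 48, 48),
#'                                     n_trees = 1, rng_seed = 7))
#' mean(ph$volume$labels == 2)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  withr::with_seed(spec$rng_seed, {
    d <- spec$shape_voxels
    vs <- spec$voxel_size
    extent <- d * vs
    n_vox <- prod(d)

    if (spec$scaffold_volume_fraction > 0) {
      labels <- array(1L, d)
      solid <- n_vox
      target <- spec$scaffold_volume_fraction * n_vox
      guard <- 0
      while (solid > target && guard < 5000) {
        r <- runif(1, spec$pore_radius_range[1], spec$pore_radius_range[2])
        # cap the pore by the remaining excess so the final solid fraction
        # lands near the target instead of overshooting with one big pore
        r_cap <- (3 * (solid - target) * vs^3 / (4 * pi))^(1 / 3)
        r <- min(r, max(r_cap, spec$pore_radius_range[1] / 2))
        p <- runif(3, 0, extent)
        before <- solid
        labels <- stamp_sphere(labels, p, r, vs, 0L)
        solid <- sum(labels == 1L)
        guard <- guard + if (solid == before) 1 else 0
      }
    } else {
      labels <- array(0L, d)
    }

    pts <- grow_trees(spec)
    if (nrow(pts) > 0) {
      # stamp spheres at sub-voxel spacing along each segment so the tube
      # surface is as smooth as the voxel grid permits (a coarser spacing
      # leaves helical surface ridges that disturb thinning)
      for (seg in unique(pts$segment)) {
        sel <- which(pts$segment == seg)
        p <- as.matrix(pts[sel, c("x", "y", "z")])
        r <- pts$radius[sel]
        for (i in seq_len(nrow(p))) {
          if (i > 1) {
            for (f in c(0.25, 0.5, 0.75)) {
              labels <- stamp_sphere(labels,
                                     p[i - 1, ] + f * (p[i, ] - p[i - 1, ]),
                                     r[i - 1] + f * (r[i] - r[i - 1]),
                                     vs, 2L)
            }
          }
          labels <- stamp_sphere(labels, p[i, ], r[i], vs, 2L)
        }
      }
    }

    truth <- structure(list(points = pts, extent_um = extent,
                            voxel_size = vs,
                            entry_face = spec$root_entry_face),
                       class = "vessel_tree_truth")
    list(volume = labeled_volume(labels, vs), truth = truth)
  })
}

#' @export
print.vessel_tree_truth <- function(x, ...) {
  cat(sprintf("vessel_tree_truth: %d tree(s), %d segment(s), %d points\n",
              length(unique(x$points$tree)),
              length(unique(x$points$segment)), nrow(x$points)))
  invisible(x)
}

#' Ground-truth depth profile from vessel centerlines
#'
#' Counts, for each slice plane along an axis, the centerline crossings per
#' diameter class using the analytic local diameter (twice the interpolated
#' radius at the crossing point). This is the exact oracle against which the
#' voxel-based [per_slice_counts()] is validated. Slice `k` corresponds to
#' the plane at depth `(k - 1/2) * slice_thickness`; the reported depth is
#' `k * slice_thickness`.
#'
#' @param truth a `vessel_tree_truth` from [generate_phantom()]
#' @param axis slicing axis (`"x"`, `"y"` or `"z"`)
#' @param slice_thickness slice spacing in micrometers (default: the
#'   phantom voxel size)
#' @param classes a [size_class_config()]
#' @param n_slices number of slices (default: covers the phantom extent)
#' @return a `depth_profile` data frame with columns `slice`, `depth_um`,
#'   `v_small`, `v_large`, `v_total`
#' @export
truth_depth_profile <- function(truth, axis = "z", slice_thickness = NULL,
                                classes = size_class_config(),
                                n_slices = NULL) {
  stopifnot(inherits(truth, "vessel_tree_truth"))
  ax <- axis_index(axis)
  if (is.null(slice_thickness)) slice_thickness <- truth$voxel_size
  check_scalar_positive(slice_thickness, "slice_thickness")
  if (is.null(n_slices))
    n_slices <- ceiling(truth$extent_um[ax] / slice_thickness)
  planes <- (seq_len(n_slices) - 0.5) * slice_thickness

  v_small <- v_large <- v_total <- integer(n_slices)
  pts <- truth$points
  if (nrow(pts) > 0) {
    coord <- pts[[c("x", "y", "z")[ax]]]
    for (seg in unique(pts$segment)) {
      sel <- which(pts$segment == seg)
      cz <- coord[sel]
      rr <- pts$radius[sel]
      if (length(cz) < 2) next
      z1 <- cz[-length(cz)]; z2 <- cz[-1]
      r1 <- rr[-length(rr)]; r2 <- rr[-1]
      for (k in seq_len(n_slices)) {
        zc <- planes[k]
        hit <- (z1 < zc & zc <= z2) | (z2 < zc & zc <= z1)
        if (!any(hit)) next
        frac <- (zc - z1[hit]) / (z2[hit] - z1[hit])
        dia <- 2 * (r1[hit] + frac * (r2[hit] - r1[hit]))
        v_total[k] <- v_total[k] + length(dia)
        v_small[k] <- v_small[k] + sum(dia >= classes$small_range[1] &
                                         dia < classes$small_range[2])
        v_large[k] <- v_large[k] + sum(dia >= classes$large_range[1] &
                                         dia <= classes$large_range[2])
      }
    }
  }
  new_depth_profile(v_small, v_large, v_total, slice_thickness, axis,
                    source = "truth")
}

new_depth_profile <- function(v_small, v_large, v_total, slice_thickness,
                              axis, source, sections = NULL) {
  n <- length(v_small)
  df <- data.frame(slice = seq_len(n),
                   depth_um = seq_len(n) * slice_thickness,
                   v_small = as.integer(v_small),
                   v_large = as.integer(v_large),
                   v_total = as.integer(v_total))
  structure(df, class = c("depth_profile", "data.frame"),
            slice_thickness = slice_thickness, axis = axis,
            source = source, sections = sections)
}
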