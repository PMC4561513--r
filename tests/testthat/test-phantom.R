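test_that("spec validation names the offending field", {
  expect_error(phantom_spec(diameter_range = c(1, 20)), "diameter_range")
  expect_error(phantom_spec(scaffold_volume_fraction = 1),
               "scaffold_volume_fraction")
  expect_error(phantom_spec(shape_voxels = c(8, 32, 32)), "shape_voxels")
  expect_error(phantom_spec(taper_factor = 0), "taper_factor")
  expect_error(phantom_spec(root_entry_face = "w-"), "root_entry_face")
})

test_that("n_trees = 0 gives an empty vessel compartment and empty truth", {
  ph <- generate_phantom(phantom_spec(shape_voxels = c(24, 24, 24),
                                      n_trees = 0, rng_seed = 1))
  expect_equal(sum(ph$volume$labels == 2L), 0)
  expect_equal(nrow(ph$truth$points), 0)
  tp <- truth_depth_profile(ph$truth)
  expect_true(all(tp$v_total == 0))
  expect_equal(nrow(tp), 24)
})

test_that("unbranched tube is one polyline with one cross-section per slice", {
  ph <- generate_phantom(straight_phantom_spec(n = 40L, seed = 7L))
  expect_equal(length(unique(ph$truth$points$segment)), 1L)
  m <- vessel_mask(ph$volume$labels == 2L, ph$volume$voxel_size)
  pr <- per_slice_counts(m)
  expect_true(all(pr$v_total == 1L))
  tp <- truth_depth_profile(ph$truth)
  expect_true(all(tp$v_total == 1L))
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  sp <- phantom_spec(shape_voxels = c(64, 64, 64), n_trees = 2, rng_seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$labels, b$volume$labels)
  expect_identical(a$truth$points, b$truth$points)
})

test_that("vessel voxel count matches the analytic tube volume within 15%", {
  for (seed in c(3L, 9L)) {
    ph <- generate_phantom(straight_phantom_spec(n = 40L, seed = seed))
    r <- ph$truth$points$radius[1]
    vs <- ph$volume$voxel_size
    analytic <- pi * r^2 * (40 * vs) / vs^3
    expect_lt(abs(sum(ph$volume$labels == 2L) - analytic) / analytic, 0.15)
  }
})

test_that("truth profile counts a tapered Y-tree by size class", {
  truth <- make_y_truth(d_parent = 18, d_child = 12, z_split = 15)
  tp <- truth_depth_profile(truth, slice_thickness = 1,
                            classes = size_class_config())
  before <- tp$depth_um < 15
  after <- tp$depth_um > 16
  expect_true(all(tp$v_small[before] == 0L & tp$v_large[before] == 1L))
  expect_true(all(tp$v_small[after] == 2L & tp$v_large[after] == 0L))
})

test_that("classes are exhaustive when all diameters lie within [10, 20]", {
  ph <- generate_phantom(phantom_spec(shape_voxels = c(64, 64, 64),
                                      n_trees = 2, rng_seed = 5))
  tp <- truth_depth_profile(ph$truth)
  expect_true(all(tp$v_total == tp$v_small + tp$v_large))
})
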