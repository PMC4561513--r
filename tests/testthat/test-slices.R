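test_that("axis-aligned tubes are classed by their true diameter", {
  for (case in list(list(d = 12, col = "v_small"),
                    list(d = 18, col = "v_large"))) {
    m <- vessel_mask(make_tube_mask(c(48, 48, 16), radius = case$d / 2,
                                    voxel_size = 0.5), 0.5)
    pr <- per_slice_counts(m)
    expect_true(all(pr[[case$col]] == 1L))
    expect_true(all(pr$v_total == 1L))
  }
})

test_that("an oblique tube still counts once but with inflated diameter", {
  # tube tilted 60 degrees from the slicing axis: elliptical sections with
  # equivalent diameter inflated by ~ 1/sqrt(cos 60) = sqrt(2)
  dims <- c(96L, 32L, 40L)
  m <- array(FALSE, dims)
  z0 <- 4; z1 <- 36
  dz <- z1 - z0
  dx <- dz * tan(60 * pi / 180)
  m <- stamp_segment(m, c(16, 16, z0), c(16 + dx, 16, z1), radius = 6)
  pr <- per_slice_counts(vessel_mask(m, 1))
  mid <- 12:28 # away from the capped ends
  expect_true(all(pr$v_total[mid] == 1L))
  dia <- vapply(attr(pr, "sections")[mid],
                function(a) 2 * sqrt(max(a) / pi), numeric(1))
  expect_equal(mean(dia), 12 / sqrt(cos(60 * pi / 180)), tolerance = 0.06)
})

test_that("an empty mask yields an all-zero profile", {
  pr <- per_slice_counts(vessel_mask(array(FALSE, c(8, 8, 8)), 1))
  expect_true(all(pr$v_total == 0))
  expect_equal(nrow(pr), 8)
})

test_that("an invalid axis is rejected", {
  m <- vessel_mask(array(FALSE, c(8, 8, 8)), 1)
  expect_error(per_slice_counts(m, axis = "w"), "axis")
})

test_that("mask counts equal the analytic truth on straight phantoms", {
  ph <- generate_phantom(straight_phantom_spec(n = 80L, n_trees = 2L,
                                               seed = 13L))
  m <- vessel_mask(ph$volume$labels == 2L, ph$volume$voxel_size)
  pr <- per_slice_counts(m)
  tp <- truth_depth_profile(ph$truth)
  expect_identical(pr$v_small, tp$v_small)
  expect_identical(pr$v_large, tp$v_large)
  expect_identical(pr$v_total, tp$v_total)
})

test_that("out-of-class components count toward the total only", {
  m <- make_tube_mask(c(48, 48, 8), radius = 6) # 12 um at 1 um voxels
  m[40:42, 40:42, ] <- TRUE                     # ~3 um speck: unclassed
  pr <- per_slice_counts(vessel_mask(m, 1))
  expect_true(all(pr$v_total == 2L))
  expect_true(all(pr$v_small + pr$v_large == 1L))
  expect_true(all(pr$v_total >= pr$v_small + pr$v_large))
})

test_that("slicing along x and y matches the tube orientation", {
  m <- aperm(make_tube_mask(c(24, 24, 16), radius = 5), c(3, 1, 2))
  pr <- per_slice_counts(vessel_mask(m, 1), axis = "x")
  expect_true(all(pr$v_total == 1L))
  expect_equal(nrow(pr), 16)
})
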