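test_that("a constant volume yields an empty mask under Otsu", {
  m <- segment_vessels(array(0.7, c(16, 16, 16)), voxel_size = 1)
  expect_false(any(m$mask))
  expect_identical(m$provenance$method, "otsu")
})

test_that("Otsu separates a clean noisy tube from background", {
  tube <- make_tube_mask(c(32, 32, 32), radius = 6)
  vol <- tube + 0.05 * withr::with_seed(2, array(rnorm(32^3), c(32, 32, 32)))
  m <- segment_vessels(vol, voxel_size = 1)
  recall <- sum(m$mask & tube) / sum(tube)
  fp <- sum(m$mask & !tube) / max(sum(m$mask), 1)
  expect_gte(recall, 0.95)
  expect_lte(fp, 0.05)
})

test_that("small components are removed; oversize floor empties the mask", {
  tube <- make_tube_mask(c(24, 24, 24), radius = 4)
  tube[2, 2, 2] <- TRUE # isolated speck
  m <- segment_vessels(tube + 0, voxel_size = 1, threshold = 0.5,
                       opening = FALSE, min_component_voxels = 27L)
  expect_equal(sum(m$mask), sum(make_tube_mask(c(24, 24, 24), radius = 4)))
  m2 <- segment_vessels(tube + 0, voxel_size = 1, threshold = 0.5,
                        min_component_voxels = 1e7)
  expect_false(any(m2$mask))
})

test_that("non-finite voxels are rejected", {
  v <- array(1, c(8, 8, 8))
  v[1] <- NA
  expect_error(segment_vessels(v, voxel_size = 1), "finite")
})

test_that("fixed thresholds are honored and recorded", {
  v <- array(0, c(8, 8, 8))
  v[4, 4, ] <- 2
  m <- segment_vessels(v, voxel_size = 1, threshold = 1, opening = FALSE,
                       min_component_voxels = 1L)
  expect_equal(sum(m$mask), 8)
  expect_identical(m$provenance$method, "fixed")
  expect_identical(m$provenance$threshold, 1)
})
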