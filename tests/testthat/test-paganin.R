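geom <- imaging_geometry() # 24 keV, 5 cm, 0.64 um

test_that("empty beam propagates to unit intensity", {
  Tz <- matrix(0, 32, 32)
  expect_equal(forward_propagate(Tz, geom, pad = "none"),
               matrix(1, 32, 32), tolerance = 1e-12)
  expect_equal(forward_propagate(Tz, geom, pad = "reflect"),
               matrix(1, 32, 32), tolerance = 1e-12)
})

test_that("at vanishing distance the model reduces to Beer-Lambert", {
  g0 <- imaging_geometry(distance = 1e-9)
  t0 <- 10
  I <- forward_propagate(matrix(t0, 32, 32), g0, pad = "none")
  expect_equal(I, matrix(exp(-g0$mu * t0), 32, 32), tolerance = 1e-9)
  Tr <- paganin_retrieve(I, g0, pad = "none")
  expect_equal(Tr, matrix(t0, 32, 32), tolerance = 1e-6)
})

test_that("a sharp edge produces phase-contrast fringes", {
  Te <- matrix(0, 64, 64)
  Te[, 33:64] <- 10
  I <- forward_propagate(Te, geom)
  expect_gt(max(I), 1)                 # overshoot on the thin side
  expect_lt(min(I), exp(-geom$mu * 10)) # undershoot on the thick side
})

test_that("retrieval inverts propagation to near machine precision", {
  for (seed in 1:5) {
    Tm <- band_limited_map(64, seed)
    Tr <- paganin_retrieve(forward_propagate(Tm, geom, pad = "none"),
                           geom, pad = "none")
    expect_lt(max(abs(Tr - Tm)) / max(abs(Tm)), 1e-6)
  }
})

test_that("unit intensity retrieves zero thickness", {
  Tr <- paganin_retrieve(matrix(1, 32, 32), geom, pad = "none")
  expect_equal(Tr, matrix(0, 32, 32), tolerance = 1e-9)
})

test_that("the retrieval filter is a low pass", {
  x <- withr::with_seed(11, matrix(rnorm(64 * 64), 64))
  x <- x - mean(x)
  y <- microvasq:::apply_filter(x, geom, pad = "none", inverse = TRUE)
  expect_lt(stats::var(as.vector(y)), stats::var(as.vector(x)))
})

test_that("nonpositive intensities are rejected with the pixel named", {
  I <- matrix(1, 8, 8)
  I[3, 5] <- 0
  expect_error(paganin_retrieve(I, geom), "\\(3, 5\\)")
})
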