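angles180 <- seq(0, 180, length.out = 201)[-201]

test_that("degenerate inputs are handled: zero slice, empty angles", {
  z <- matrix(0, 32, 32)
  expect_equal(radon_project(z, angles180), {
    s <- radon_project(z, angles180); s[] <- 0; s
  })
  expect_error(radon_project(z, numeric(0)), "empty")
  expect_error(radon_project(matrix(0, 4, 6), angles180), "square")
})

test_that("a centered disk projects identically at every angle", {
  n <- 128
  xy <- (1:n) - (n + 1) / 2
  disk <- (outer(xy^2, xy^2, `+`) <= (n / 4)^2) + 0
  s <- radon_project(disk, angles180)
  dev <- apply(s, 1, function(row) diff(range(row)))
  expect_lt(max(dev) / max(s), 0.05) # bilinear chord discretization
})

test_that("each projection conserves the total mass of the slice", {
  # support restricted to the inscribed circle so no mass leaves the
  # rotated field of view
  n <- 64
  xy <- (1:n) - (n + 1) / 2
  inside <- outer(xy^2, xy^2, `+`) <= (n / 2 - 2)^2
  sl <- band_limited_map(n, 4, cutoff = 0.1, height = 1) * inside
  s <- radon_project(sl, angles180, pixel_size = 2)
  expect_equal(colSums(s) / 2, rep(sum(sl), ncol(s)), tolerance = 0.005)
})

test_that("radon and FBP are linear operators", {
  a <- band_limited_map(32, 1, height = 1)
  b <- band_limited_map(32, 2, height = 1)
  sa <- radon_project(a, angles180)
  sb <- radon_project(b, angles180)
  sab <- radon_project(2 * a - 3 * b, angles180)
  expect_equal(sab, 2 * sa - 3 * sb, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fbp_reconstruct(2 * sa - 3 * sb, angles180),
               2 * fbp_reconstruct(sa, angles180) -
                 3 * fbp_reconstruct(sb, angles180),
               tolerance = 1e-10)
})

test_that("FBP recovers a disk phantom with RMSE below 5% of range", {
  n <- 128
  xy <- (1:n) - (n + 1) / 2
  disk <- (outer(xy^2, xy^2, `+`) <= (n / 4)^2) +
    0.5 * (outer((xy - 10)^2, xy^2, `+`) <= (n / 8)^2)
  ang <- seq(0, 180, length.out = 401)[-401]
  rec <- fbp_reconstruct(radon_project(disk, ang), ang)
  expect_lt(sqrt(mean((rec - disk)^2)) / diff(range(disk)), 0.05)
})

test_that("insufficient angular coverage is an error", {
  s <- radon_project(matrix(1, 32, 32), seq(0, 90, by = 1))
  expect_error(fbp_reconstruct(s, seq(0, 90, by = 1)), "coverage")
  expect_error(fbp_reconstruct(s[, 1, drop = FALSE], 0), "at least 2")
})

test_that("a full turn folds onto the half turn", {
  n <- 64
  sl <- band_limited_map(n, 8, cutoff = 0.08, height = 1)
  a180 <- seq(0, 180, length.out = 181)[-181]
  a360 <- seq(0, 360, length.out = 361)[-361]
  r180 <- fbp_reconstruct(radon_project(sl, a180), a180)
  r360 <- fbp_reconstruct(radon_project(sl, a360), a360)
  expect_equal(r360, r180, tolerance = 0.02)
})
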