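test_that("spec validation enforces the instrument q range and fractions", {
  expect_error(diffraction_sim_spec(q_c = 0.2), "q_c")
  expect_error(diffraction_sim_spec(q_c = 31), "q_c")
  expect_error(diffraction_sim_spec(aligned_fraction = 1.2),
               "aligned_fraction")
  expect_error(diffraction_sim_spec(background = list(model = "cubic")),
               "background")
})

test_that("zero aligned fraction gives an azimuthally isotropic ring", {
  p <- simulate_diffraction_pattern(
    diffraction_sim_spec(aligned_fraction = 0, poisson_noise = FALSE))
  ap <- azimuthal_integrate(p)
  expect_lt(diff(range(ap$intensity)) / mean(ap$intensity), 0.02)
})

test_that("zero amplitude leaves only the background", {
  spec <- diffraction_sim_spec(amplitude = 0, poisson_noise = FALSE)
  p <- simulate_diffraction_pattern(spec)
  maps <- q_map(attr(p, "geometry"))
  bg <- microvasq:::eval_background(spec$background, maps$q)
  expect_equal(unclass(p), bg, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noise-free patterns are exactly symmetric under Phi -> Phi+180", {
  p <- simulate_diffraction_pattern(
    diffraction_sim_spec(poisson_noise = FALSE, orientation_angle = 47))
  n <- nrow(p)
  expect_equal(unclass(p), unclass(p)[n:1, n:1], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("noisy simulation is reproducible for a fixed seed", {
  s <- diffraction_sim_spec(rng_seed = 77)
  expect_identical(unclass(simulate_diffraction_pattern(s)),
                   unclass(simulate_diffraction_pattern(s)))
})

test_that("a ring outside the detector coverage is an error", {
  expect_error(simulate_diffraction_pattern(
    diffraction_sim_spec(q_c = 25)), "coverage")
})

test_that("scan grids validate shapes and honor per-position parameters", {
  base <- diffraction_sim_spec(poisson_noise = FALSE)
  expect_error(simulate_scan_grid(base, matrix(1, 2, 2), matrix(0, 2, 3),
                                  matrix(0.5, 2, 2)), "shape")
  sc <- simulate_scan_grid(base, matrix(1, 2, 2), matrix(30, 2, 2),
                           matrix(0.5, 2, 2))
  expect_length(sc$patterns, 4)
  # constant maps + no noise: all patterns identical
  expect_equal(unclass(sc$patterns[[1]]), unclass(sc$patterns[[4]]),
               ignore_attr = TRUE)
  # zero amount at a position: no ring there
  am <- matrix(1, 2, 2); am[1, 1] <- 0
  sc0 <- simulate_scan_grid(base, am, matrix(30, 2, 2), matrix(0.5, 2, 2))
  spec0 <- diffraction_sim_spec(amplitude = 0, poisson_noise = FALSE)
  maps <- q_map(sc0$geometry)
  bg <- microvasq:::eval_background(spec0$background, maps$q)
  expect_equal(unclass(sc0$patterns[[1]]), bg, tolerance = 1e-12,
               ignore_attr = TRUE)
})
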