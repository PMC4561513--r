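test_that("q mapping matches scalar closed forms", {
  g <- detector_geometry(wavelength_nm = 0.0976, distance_mm = 1100,
                         pixel_size_mm = 0.05, detector_px = c(256, 256),
                         beam_center = c(128, 128))
  maps <- q_map(g)
  expect_equal(maps$q[128, 128], 0)
  # pixel 100 px to the right of the beam center: scalar arithmetic oracle
  r_mm <- 100 * 0.05
  q_hand <- 4 * pi * sin(atan(r_mm / 1100) / 2) / 0.0976
  expect_equal(maps$q[228, 128], q_hand, tolerance = 1e-12)
  expect_equal(maps$phi[228, 128], 0)
  expect_equal(maps$phi[128, 228], 90)
  # q increases strictly with pixel radius along a detector row
  expect_true(all(diff(maps$q[128:256, 128]) > 0))
})

test_that("radial integration: flat patterns, conservation, ring location", {
  g <- detector_geometry(detector_px = c(64, 64), pixel_size_mm = 1,
                         distance_mm = 200)
  flat <- matrix(3, 64, 64)
  rp <- radial_integrate(flat, g, n_bins = 30)
  expect_true(all(abs(rp$intensity[rp$n_pixels > 0] - 3) < 1e-12))
  # binned sums conserve the total counts of the covered region
  expect_equal(sum(rp$sum), sum(flat))
  expect_error(radial_integrate(flat, g, q_range = c(100, 200)),
               "coverage")
  # a synthetic ring peaks in the bin containing q_c
  spec <- diffraction_sim_spec(poisson_noise = FALSE)
  p <- simulate_diffraction_pattern(spec)
  rp2 <- radial_integrate(p, n_bins = 120, q_range = c(0.5, 8))
  net <- rp2$intensity - stats::runmed(rp2$intensity, 31)
  expect_lt(abs(rp2$q[which.max(net)] - 5.6), diff(rp2$q[1:2]) * 2)
})

test_that("azimuthal integration reflects the ring orientation", {
  g0 <- diffraction_sim_spec(poisson_noise = FALSE, orientation_angle = 30)
  p <- simulate_diffraction_pattern(g0)
  ap <- azimuthal_integrate(p)
  peaks <- sort(ap$phi[order(ap$intensity, decreasing = TRUE)][1:2])
  expect_lt(abs(peaks[1] - 30), 10)
  expect_lt(abs(peaks[2] - 210), 10)
  expect_error(azimuthal_integrate(p, q_window = c(100, 101)), "empty")
  # isotropic pattern: flat azimuthal profile
  p0 <- simulate_diffraction_pattern(
    diffraction_sim_spec(aligned_fraction = 0, poisson_noise = FALSE))
  ap0 <- azimuthal_integrate(p0)
  expect_lt(diff(range(ap0$intensity)) / mean(ap0$intensity), 0.02)
})

test_that("noiseless peak fits recover the generator parameters to 0.1%", {
  for (bg in c("poly2", "powerlaw")) {
    spec <- diffraction_sim_spec(
      poisson_noise = FALSE,
      background = if (bg == "poly2") list(model = "poly2",
                                           coeffs = c(150, -12, 0.3))
      else list(model = "powerlaw", coeffs = c(400, 1.1)))
    p <- simulate_diffraction_pattern(spec)
    rp <- radial_integrate(p, n_bins = 150, q_range = c(0.5, 8))
    fit <- fit_collagen_peak(rp, background = bg)
    expect_identical(fit$flag, "ok")
    expect_lt(abs(fit$q_c - 5.6) / 5.6, 1e-3)
    expect_lt(abs(fit$sigma_q - 0.35) / 0.35, 0.05)
    # D q_c = 2 pi exactly, by construction
    expect_identical(fit$lateral_spacing, 2 * pi / fit$q_c)
  }
})

test_that("peak-free windows are flagged, not errors", {
  spec <- diffraction_sim_spec(amplitude = 0, poisson_noise = FALSE)
  p <- simulate_diffraction_pattern(spec)
  rp <- radial_integrate(p, n_bins = 150, q_range = c(0.5, 8))
  fit <- fit_collagen_peak(rp)
  expect_identical(fit$flag, "no_peak")
  expect_lt(fit$peak_area, 1e-6)
  expect_error(fit_collagen_peak(rp, window = c(4.6, 4.65)), "8 non-empty")
})

test_that("orientation fits recover angles across the half circle", {
  for (ang in c(10, 75, 120, 170)) {
    p <- simulate_diffraction_pattern(
      diffraction_sim_spec(orientation_angle = ang, rng_seed = ang))
    orf <- fit_orientation(azimuthal_integrate(p))
    expect_identical(orf$flag, "ok")
    expect_lt(abs(microvasq:::wrap90(orf$orientation_angle - ang)), 2)
  }
})

test_that("flat azimuthal profiles give exactly zero degree", {
  ap <- structure(data.frame(phi = (1:72 - 0.5) * 5, intensity = 40,
                             n_pixels = 10L, sum = 400),
                  class = c("azimuthal_profile", "data.frame"))
  orf <- fit_orientation(ap)
  expect_identical(orf$degree, 0)
  expect_identical(orf$flag, "flat")
})

test_that("the orientation degree is a scale-invariant ratio", {
  p <- simulate_diffraction_pattern(
    diffraction_sim_spec(poisson_noise = FALSE))
  ap1 <- azimuthal_integrate(p)
  ap2 <- azimuthal_integrate(2 * p, geom = attr(p, "geometry"))
  d1 <- fit_orientation(ap1)$degree
  d2 <- fit_orientation(ap2)$degree
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("the degree increases with the true aligned fraction", {
  degs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(af) {
    p <- simulate_diffraction_pattern(
      diffraction_sim_spec(aligned_fraction = af, poisson_noise = FALSE))
    fit_orientation(azimuthal_integrate(p))$degree
  }, numeric(1))
  expect_true(all(diff(degs) > 0))
})
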