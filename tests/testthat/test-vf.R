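test_that("default section weights reproduce the class-midpoint areas", {
  expect_equal(default_section_weight(c(10, 15)), 123)
  expect_equal(default_section_weight(c(15, 20)), 240)
  expect_equal(default_section_weight(c(10, 15), round = FALSE),
               pi * 6.25^2)
  expect_error(default_section_weight(c(0, 0)), "lo < hi")
  expect_error(default_section_weight(c(5, 5)), "lo < hi")
})

test_that("class configuration enforces contiguous ranges", {
  expect_error(size_class_config(small_range = c(10, 14),
                                 large_range = c(15, 20)), "contiguous")
  cc <- size_class_config()
  expect_equal(cc$small_section, pi * 6.25^2)
  expect_equal(cc$large_section, pi * 8.75^2)
})

profile_from_counts <- function(v_small, v_large, dz = 1) {
  microvasq:::new_depth_profile(v_small, v_large, v_small + v_large,
                                dz, "z", source = "test")
}

test_that("VF closed forms: empty, full-depth small vessel, half-depth large", {
  n <- 50
  cc <- size_class_config(small_section = 123, large_section = 240,
                          total_depth_norm = n)
  expect_equal(vascularization_factor(
    profile_from_counts(rep(0L, n), rep(0L, n)), cc), 0)
  expect_equal(vascularization_factor(
    profile_from_counts(rep(1L, n), rep(0L, n)), cc), 123)
  two_large_half <- profile_from_counts(rep(0L, n),
                                        c(rep(2L, n / 2), rep(0L, n / 2)))
  expect_equal(vascularization_factor(two_large_half, cc), 240)
})

test_that("VF is linear in the counts", {
  vs <- withr::with_seed(1, rpois(30, 2))
  vl <- withr::with_seed(2, rpois(30, 1))
  cc <- size_class_config()
  v1 <- vascularization_factor(profile_from_counts(vs, vl), cc)
  v2 <- vascularization_factor(profile_from_counts(2L * vs, 2L * vl), cc)
  expect_equal(v2, 2 * v1)
})

test_that("VF is invariant under slice-thickness refinement", {
  vs <- c(1L, 1L, 2L, 0L, 3L)
  vl <- c(0L, 1L, 1L, 1L, 0L)
  cc <- size_class_config(total_depth_norm = 5)
  coarse <- profile_from_counts(vs, vl, dz = 1)
  fine <- profile_from_counts(rep(vs, each = 2), rep(vl, each = 2), dz = 0.5)
  expect_equal(vascularization_factor(coarse, cc),
               vascularization_factor(fine, cc))
})

test_that("by default VF normalizes by the analyzed depth", {
  cc <- size_class_config()
  pr <- profile_from_counts(rep(1L, 40), rep(0L, 40), dz = 0.64)
  expect_equal(vascularization_factor(pr, cc), cc$small_section)
})

test_that("sample summary is internally consistent with its profile", {
  ph <- generate_phantom(straight_phantom_spec(n = 40L, seed = 7L))
  m <- vessel_mask(ph$volume$labels == 2L, ph$volume$voxel_size)
  pr <- per_slice_counts(m)
  g <- skeletonize_3d(m)
  qs <- summarize_sample(m, pr, g)
  expect_equal(qs$total_v_small, sum(pr$v_small))
  expect_equal(qs$total_v_large, sum(pr$v_large))
  expect_equal(qs$n_branches, 1L)
  true_d <- 2 * ph$truth$points$radius[1]
  expect_equal(qs$min_diameter_um, true_d, tolerance = 0.1)
  expect_equal(qs$max_section_um2, max(unlist(attr(pr, "sections"))))
})

test_that("an empty mask summarizes to zeros", {
  m <- vessel_mask(array(FALSE, c(8, 8, 8)), 1)
  pr <- per_slice_counts(m)
  qs <- summarize_sample(m, pr, skeletonize_3d(m))
  expect_equal(qs$max_section_um2, 0)
  expect_equal(qs$min_diameter_um, 0)
  expect_equal(qs$n_branches, 0L)
  expect_equal(qs$vf_um2, 0)
})
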