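test_that("a straight tube reduces to one branch with two endpoints", {
  g <- skeletonize_3d(vessel_mask(make_tube_mask(c(24, 24, 32), radius = 4),
                                  1))
  sc <- skeleton_counts(g)
  expect_equal(sc$n_endpoints, 2L)
  expect_equal(sc$n_junctions, 0L)
  expect_equal(sc$n_edges, 1L)
  expect_equal(sc$n_cycles, 0L)
  expect_equal(count_branches(g), 1L)
})

test_that("a Y-shaped tube gives 3 endpoints, 1 junction, 3 branches", {
  g <- skeletonize_3d(vessel_mask(make_y_mask(), 1))
  gp <- microvasq:::prune_spurs(g, 5)
  expect_equal(sum(gp$nodes$kind == "endpoint"), 3L)
  expect_equal(sum(gp$nodes$kind == "junction"), 1L)
  expect_equal(count_branches(g), 3L)
})

test_that("a ring reduces to a single cycle with no endpoints", {
  g <- skeletonize_3d(vessel_mask(make_ring_mask(), 1))
  sc <- skeleton_counts(g)
  expect_equal(sc$n_endpoints, 0L)
  expect_equal(sc$n_junctions, 0L)
  expect_equal(sc$n_cycles, 1L)
})

test_that("short endpoint spurs are pruned before branch counting", {
  # synthetic graph: Y (three 12 um branches at junction node 1) plus a
  # 2 um spur; pruning at 5 um removes only the spur
  g <- structure(list(
    nodes = data.frame(id = 1:5, x = 0, y = 0, z = 0, n_voxels = 1L,
                       degree = c(4L, 1L, 1L, 1L, 1L),
                       kind = c("junction", rep("endpoint", 4)),
                       radius_um = 3),
    edges = data.frame(id = 1:4, from = 1L, to = 2:5,
                       length_um = c(12, 12, 12, 2), n_voxels = 10L),
    paths = NULL, voxels = matrix(0L, 0, 3), dims = c(1L, 1L, 1L),
    voxel_size = 1), class = "skeleton_graph")
  expect_equal(count_branches(g, min_branch_length = 5), 3L)
  expect_equal(count_branches(g, min_branch_length = 0), 4L)
  expect_error(count_branches(g, min_branch_length = -1), "non-negative")
})

test_that("pruning a mid-line nub re-joins the interrupted branch", {
  g <- structure(list(
    nodes = data.frame(id = 1:4, x = 0, y = 0, z = 0, n_voxels = 1L,
                       degree = c(1L, 3L, 1L, 1L),
                       kind = c("endpoint", "junction", "endpoint",
                                "endpoint"),
                       radius_um = 3),
    edges = data.frame(id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                       length_um = c(15, 15, 2), n_voxels = 10L),
    paths = NULL, voxels = matrix(0L, 0, 3), dims = c(1L, 1L, 1L),
    voxel_size = 1), class = "skeleton_graph")
  expect_equal(count_branches(g, min_branch_length = 5), 1L)
})

test_that("branch counts are invariant under 90-degree rotations", {
  for (mask in list(make_y_mask(), make_tube_mask(c(24, 24, 32), 4))) {
    n0 <- count_branches(skeletonize_3d(vessel_mask(mask, 1)))
    rot_z <- aperm(mask, c(2, 1, 3))[dim(mask)[2]:1, , ] # 90 deg about z
    rot_y <- aperm(mask, c(3, 2, 1))[, , dim(mask)[1]:1] # 90 deg about y
    expect_equal(count_branches(skeletonize_3d(vessel_mask(rot_z, 1))), n0)
    expect_equal(count_branches(skeletonize_3d(vessel_mask(rot_y, 1))), n0)
  }
})

test_that("node radii track the tube radius via the distance transform", {
  g <- skeletonize_3d(vessel_mask(make_tube_mask(c(24, 24, 32), radius = 5),
                                  1))
  expect_equal(mean(g$nodes$radius_um), 5, tolerance = 0.25)
})

test_that("an empty mask produces an empty graph", {
  g <- skeletonize_3d(vessel_mask(array(FALSE, c(8, 8, 8)), 1))
  expect_equal(nrow(g$nodes), 0L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(count_branches(g), 0L)
})
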