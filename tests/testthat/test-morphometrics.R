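test_that("truncated-cone surface and volume match the closed form", {
  # single sub-segment with r = R = 1 um and h = 1 um
  m <- parse_swc(c("1 1 0 0 0 1 -1", "2 3 0 0 1 1 1"))
  st <- suppressWarnings(compute_statistics(geometry_tables(m)))
  expect_equal(st[["surface"]], 2 * pi, tolerance = 1e-12)
  expect_equal(st[["volume"]], pi, tolerance = 1e-12)
  expect_equal(st[["avg_thickness"]], 1)
})

test_that("Y-tree statistics match the hand counts", {
  st <- compute_statistics(geometry_tables(fx$y_tree))
  expect_equal(st[["n_branch_points"]], 1)
  expect_equal(st[["n_tips"]], 2)
  expect_equal(st[["n_stems"]], 1)
  expect_equal(st[["total_length"]], 4)
  expect_equal(st[["max_neurite_length"]], 3)
  expect_equal(st[["max_branch_order"]], 1)
  expect_equal(st[["max_degree"]], 3)
})

test_that("straight neurites have zero median path angle and log-tortuosity", {
  st <- suppressWarnings(compute_statistics(geometry_tables(fx$straight)))
  expect_equal(st[["median_path_angle"]], 0)
  expect_equal(st[["median_log_tortuosity"]], 0)
  # branch-angle statistics are undefined here and recorded as 0
  w <- capture_warnings(compute_statistics(geometry_tables(fx$straight)))
  expect_true(any(grepl("branch angle", w)))
  expect_equal(st[["min_branch_angle"]], 0)
})

test_that("tree asymmetry follows the weighted PSAD sum", {
  expect_equal(tree_asymmetry(fx$caterpillar4), 1.0)
  expect_equal(tree_asymmetry(fx$balanced4), 0.0)
  expect_equal(tree_asymmetry(fx$y_tree), 0.0)      # only 2 leaves: weight 0
  expect_equal(tree_asymmetry(fx$straight), 0.0)    # no branch point
})

test_that("statistics are invariant to translation and to resampling", {
  pop <- small_pop(41, n = 8)
  m <- pop$morphologies[[1]]
  st <- compute_statistics(geometry_tables(m))
  shifted <- m
  shifted$nodes$x <- shifted$nodes$x + 100
  shifted$nodes$y <- shifted$nodes$y - 42
  shifted$nodes$z <- shifted$nodes$z + 7
  st2 <- compute_statistics(geometry_tables(shifted))
  expect_equal(unclass(st2), unclass(st), tolerance = 1e-9)

  rs <- resample(m, 1)
  st3 <- compute_statistics(geometry_tables(rs))
  scale_free <- c("n_branch_points", "n_tips", "n_stems", "max_branch_order",
                  "max_degree", "tree_asymmetry")
  expect_equal(unclass(st3[scale_free]), unclass(st[scale_free]))
  expect_equal(st3[["total_length"]], st[["total_length"]], tolerance = 1e-6)
  expect_equal(st3[["max_neurite_length"]], st[["max_neurite_length"]],
               tolerance = 1e-6)
  # 99.5th percentile dominates the median
  expect_gte(st[["max_path_angle"]], st[["median_path_angle"]])
  expect_gte(st[["max_log_tortuosity"]], st[["median_log_tortuosity"]])
})

test_that("1D distributions bin as documented", {
  g <- geometry_tables(fx$y_tree)
  ed <- dataset_edges(g)
  ba <- distribution_1d(g, "branch_angles", ed)
  expect_length(ba$values, 20L)
  expect_equal(which(ba$values > 0), 11L)           # 90 deg -> 0-based bin 10
  expect_equal(sum(ba$values), 1)

  gp <- geometry_tables(fx$straight)
  bo <- distribution_1d(gp, "branch_orders", dataset_edges(gp))
  expect_true(all(bo$values == 0))                  # path graph: no BPs

  expect_error(distribution_1d(g, "nonsense", ed), "unknown")
})

test_that("Sholl profiles count circle crossings", {
  # straight radial neurite of length 5 in the xz-plane
  g <- geometry_tables(fx$straight)
  sh <- sholl_profile(g, "xz")
  expect_equal(sh, rep(1, 36))
  # both Y-tree daughters extending radially beyond the branch radius
  m <- parse_swc(c("1 1 0 0 0 1 -1",
                   "2 3 1 0 0 0.5 1",
                   "3 3 2 0.5 0 0.5 2",
                   "4 3 2 -0.5 0 0.5 2"))
  shy <- sholl_profile(geometry_tables(m), "xy")
  expect_true(all(shy %in% c(1, 2)))
  expect_equal(shy[1], 1)
  expect_equal(shy[36], 2)
  expect_true(all(diff(shy) >= 0))
})

test_that("3-star motifs count forks and grow along deciles", {
  expect_equal(star_motifs(fx$y_tree)[10], 1)         # bifurcation
  expect_equal(star_motifs(fx$trifurcation)[10], 2)   # trifurcation: 2 motifs
  pop <- small_pop(43, n = 8)
  m <- pop$morphologies[[1]]
  sm <- star_motifs(m)
  expect_true(all(diff(sm) >= 0))                     # nested sub-graphs
  a1 <- star_motifs(m, "random", n_repeats = 5, seed = 7)
  a2 <- star_motifs(m, "random", n_repeats = 5, seed = 7)
  expect_identical(a1, a2)                            # seeded determinism
  d1 <- average_maximal_distance(m, n_repeats = 5, seed = 7)
  expect_true(all(diff(d1) >= -1e-9))
})

test_that("2D distribution marginals match the shared 1D binning", {
  pop <- small_pop(47, n = 8)
  g <- geometry_tables(pop$morphologies[[3]])
  ed <- dataset_edges(g)
  for (nm in morphrep_distributions()$two_d) {
    d2 <- distribution_2d(g, nm, ed)
    expect_length(d2$values, 400L)
    expect_true(all(d2$values >= 0))
    first <- sub("_x_.*", "", nm)
    one_d_name <- switch(first, branch_angle = "branch_angles",
                         path_angle = "path_angles", thickness = "thickness")
    d1 <- distribution_1d(g, one_d_name, ed, nbins = 20L)
    expect_equal(rowSums(d2$matrix), d1$values)
  }
  # total mass equals the number of contributing records
  d2 <- distribution_2d(g, "path_angle_x_path_dist", ed)
  expect_equal(sum(d2$values), sum(!is.na(g$nodes$path_angle)))
})
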