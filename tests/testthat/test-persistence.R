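test_that("hand-traced diagrams match the elder rule", {
  # single unbranched neurite of length L: {(L, 0)}
  d <- compute_diagram(fx$straight, "path_length")
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$birth, d$death), c(5, 0))
  # Y-tree with stem 1, daughters 2 and 1: {(3,0), (2,1)}
  dy <- sort_diagram(compute_diagram(fx$y_tree, "path_length"))
  expect_equal(dy$birth, c(2, 3))
  expect_equal(dy$death, c(1, 0))
  # an embedding with z equal to path position makes z-projection coincide
  m <- fx$y_tree
  g <- geometry_tables(m)
  m$nodes$z <- g$nodes$path_dist
  m$nodes$x <- 0; m$nodes$y <- 0
  dz <- sort_diagram(compute_diagram(m, "z_projection"))
  expect_equal(dz[, c("birth", "death")], dy[, c("birth", "death")])
})

test_that("multifurcations kill all non-surviving children at once", {
  d <- compute_diagram(fx$trifurcation, "path_length")
  expect_equal(nrow(d), 3L)
  expect_equal(sum(d$death == 1), 2L)   # two younger branches die at the fork
  expect_equal(sum(d$death == 0), 1L)
})

test_that("birth ties resolve to the smaller tip id", {
  m <- parse_swc(c("1 1 0 0 0 1 -1",
                   "2 3 0 0 1 0.5 1",
                   "3 3 1 0 1 0.5 2",
                   "4 3 -1 0 1 0.5 2"))
  d <- compute_diagram(m, "path_length")
  survivor <- d$tip_id[d$death == 0]
  expect_equal(survivor, 3L)
})

test_that("diagram size, lifetime sum and the brute-force oracle agree", {
  pop <- small_pop(53, n = 8)
  for (m in pop$morphologies[1:6]) {
    n_tip <- morphrep:::n_tips(m)
    for (flt in c("radial_distance", "path_length", "branch_order",
                  "z_projection")) {
      d <- compute_diagram(m, flt)
      expect_equal(nrow(d), n_tip)
      expect_equal(sort_diagram(d), sort_diagram(oracle_diagram(m, flt)))
    }
    dp <- compute_diagram(m, "path_length")
    expect_true(all(dp$birth >= dp$death - 1e-9))
    expect_equal(sum(dp$birth - dp$death), morphrep:::total_length(m),
                 tolerance = 1e-9)
    db <- compute_diagram(m, "branch_order")
    expect_true(all(db$birth >= db$death))
  }
})

test_that("persistence images are valid densities on the fixed grid", {
  d <- compute_diagram(fx$caterpillar4, "path_length")
  img <- persistence_image_2d(d, max_birth = 5, max_death = 5)
  expect_equal(dim(img$values), c(100L, 100L))
  expect_true(all(is.finite(img$values)) && all(img$values >= 0))
  # mass concentrated near the diagram points
  am <- which(img$values == max(img$values), arr.ind = TRUE)[1, ]
  pt_b <- img$birth_grid[am[1]]; pt_d <- img$death_grid[am[2]]
  expect_lt(min(sqrt((d$birth - pt_b)^2 + (d$death - pt_d)^2)), 1.5)

  v <- persistence_image_1d(d, max_birth = 5)
  expect_length(v, 100L)
  expect_true(all(v >= 0))

  # near-singleton diagram: fallback bandwidth, argmax within a cell
  d1 <- compute_diagram(fx$straight, "path_length")
  img1 <- persistence_image_2d(d1, max_birth = 10, max_death = 10)
  am1 <- which(img1$values == max(img1$values), arr.ind = TRUE)[1, ]
  expect_equal(img1$birth_grid[am1[1]], 5, tolerance = 0.2)
  expect_equal(img1$death_grid[am1[2]], 0, tolerance = 0.2)
})

test_that("negative lifetimes are clipped before the 1D estimate", {
  m <- parse_swc(c("1 1 0 0 0 1 -1",
                   "2 3 0 0 5 0.5 1",
                   "3 3 0 0 2 0.5 2",   # descends: z below the branch point
                   "4 3 0 1 6 0.5 2"))
  d <- compute_diagram(m, "z_projection")
  expect_true(any(d$birth - d$death < 0))
  expect_message(persistence_image_1d(d, max_birth = 6), "clipped")
})
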