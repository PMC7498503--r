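test_that("soma consolidation merges somatic nodes at their centroid", {
  m <- parse_swc(c("1 1 0 0 0 2 -1",
                   "2 1 2 0 0 2 1",
                   "3 3 2 0 1 0.5 2",
                   "4 3 0 0 1 0.5 1"))
  out <- consolidate_soma(m)
  soma <- out$nodes[out$nodes$type == 1L, ]
  expect_equal(nrow(soma), 1L)
  expect_equal(c(soma$x, soma$y, soma$z), c(1, 0, 0))
  expect_equal(sum(out$nodes$parent == -1L), 1L)
  # children of removed somatic nodes hang off the new soma
  expect_equal(sort(out$nodes$parent[out$nodes$type == 3L]),
               rep(soma$id, 2))
  expect_valid_morphology(out)
})

test_that("radius threshold relabels thick nodes as somatic before grouping", {
  m <- parse_swc(c("1 2 0 0 0 1.5 -1",
                   "2 2 1 0 0 0.4 1",
                   "3 2 2 0 0 0.4 2"))
  out <- consolidate_soma(m, radius_threshold = 1)
  expect_equal(sum(out$nodes$type == 1L), 1L)
  expect_equal(out$nodes$type[out$nodes$parent == -1L], 1L)
  # an already single-soma cell is untouched
  m2 <- fx$y_tree
  expect_identical(consolidate_soma(m2), m2)
})

test_that("branch types follow the majority vote with axon winning ties", {
  m <- parse_swc(c("1 1 0 0 0 1 -1",
                   "2 2 0 0 1 0.4 1",
                   "3 2 0 0 2 0.4 2",
                   "4 3 0 0 3 0.4 3"))
  out <- harmonize_branch_types(m)
  expect_equal(out$nodes$type[-1], c(2L, 2L, 2L))   # majority axon
  tie <- parse_swc(c("1 1 0 0 0 1 -1",
                     "2 2 0 0 1 0.4 1",
                     "3 3 0 0 2 0.4 2"))
  expect_equal(harmonize_branch_types(tie)$nodes$type[-1], c(2L, 2L))
  expect_identical(harmonize_branch_types(fx$y_tree)$nodes,
                   fx$y_tree$nodes)                  # uniform: unchanged
})

test_that("resampling respects spacing, preserves length and is idempotent", {
  r <- resample(fx$straight, 1)
  expect_equal(nrow(r$nodes), 6L)
  expect_equal(sum(morphrep:::edge_lengths(r), na.rm = TRUE), 5)
  expect_true(all(morphrep:::edge_lengths(r)[-1] <= 1 + 1e-9))

  elbow <- parse_swc(c("1 1 0 0 0 1 -1",
                       "2 3 1 0 0 0.5 1",
                       "3 3 1 1 0 0.5 2"))
  re <- resample(elbow, 0.3)
  tot <- sum(morphrep:::edge_lengths(re), na.rm = TRUE)
  expect_lte(tot, 2 + 1e-9)
  expect_gte(tot, sqrt(2))

  for (m in list(fx$semicircle, fx$y_tree, fx$caterpillar4)) {
    r1 <- resample(m, 0.4)
    r2 <- resample(r1, 0.4)
    expect_equal(r1$nodes, r2$nodes, tolerance = 1e-9)
    expect_valid_morphology(r1)
  }
  expect_error(resample(fx$y_tree, 0), "spacing")
})

test_that("depth-axis smoothing reproduces cubics and damps outliers", {
  n <- 60
  s <- seq_len(n)
  ycub <- 1e-3 * s^3 - 0.05 * s^2 + 0.2 * s
  m <- morphology(data.frame(id = 1:n, type = c(1L, rep(2L, n - 1)),
                             x = s, y = ycub, z = 0, radius = 0.4,
                             parent = c(-1L, 1:(n - 1))))
  sm <- smooth_depth_axis(m, window = 21, order = 3)
  expect_equal(sm$nodes$y, ycub, tolerance = 1e-6)
  expect_equal(sm$nodes$x, m$nodes$x)                  # x untouched

  yimp <- rep(0, n); yimp[30] <- 10
  mi <- m; mi$nodes$y <- yimp
  smi <- smooth_depth_axis(mi)
  expect_lt(max(abs(smi$nodes$y)), 10)

  short <- fx$straight                                  # run of 6 << window
  expect_identical(smooth_depth_axis(short)$nodes, short$nodes)
})

test_that("centering places the soma at the origin and is idempotent", {
  m <- parse_swc(c("1 1 3 4 5 1 -1", "2 3 4 4 5 0.5 1"))
  c1 <- center_morphology(m, "soma")
  expect_equal(unlist(c1$nodes[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  expect_identical(center_morphology(c1, "soma")$nodes, c1$nodes)
  cb <- center_morphology(m, "soma_xy_with_z_offset", z_offset = -12)
  expect_equal(cb$nodes$z, c(-7, -7))
  expect_equal(cb$nodes$x, c(0, 1))
})

test_that("the preprocessing chain preserves tree invariants", {
  pop <- small_pop(11, n = 8)
  m <- pop$morphologies[[1]]
  out <- preprocess_morphology(m, "cortical")
  expect_valid_morphology(out)
  s <- morphrep:::soma_row(out)
  expect_equal(unlist(out$nodes[s, c("x", "y", "z")]),
               c(x = 0, y = 0, z = 0))
  expect_equal(sum(out$nodes$type == 1L), 1L)
})
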