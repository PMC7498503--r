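test_that("skeleton sampling produces the expected point counts", {
  seg <- parse_swc(c("1 1 0 0 0 1 -1", "2 3 0 0 1 0.5 1"))
  cl <- sample_points(seg, 0.025)
  expect_equal(nrow(cl$points), 41L)            # 40 intervals + endpoints
  # all points lie on the (here: straight) skeleton
  expect_true(all(abs(cl$points[, "x"]) < 1e-12))
  expect_true(all(cl$points[, "z"] >= 0 & cl$points[, "z"] <= 1))

  cly <- sample_points(fx$y_tree, 0.025)
  total <- morphrep:::total_length(fx$y_tree)
  expect_lt(abs(nrow(cly$points) - total / 0.025), 4)  # +- number of segments
})

test_that("normalization ranges cover the data and reject degenerate axes", {
  m <- parse_swc(c("1 1 0 0 -3 1 -1", "2 3 1 1 7 0.5 1"))
  cl <- sample_points(m, 0.1)
  rg <- fit_ranges(cl)
  expect_equal(unname(c(rg$min["z"], rg$max["z"])), c(-3, 7))
  norm <- sweep(sweep(cl$points, 2, rg$min), 2, rg$max - rg$min, "/")
  expect_true(all(norm >= 0 & norm <= 1))
  flat <- parse_swc(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.5 1"))
  expect_error(fit_ranges(sample_points(flat, 0.1)), "degenerate.*[yz]")
})

test_that("binning arithmetic and smoothing behave as specified", {
  # a single point at normalized 0.5: bin floor((0.5+0.1)/0.012) (0-based)
  cl <- structure(list(points = cbind(x = 0.5, y = 0.5, z = 0.5),
                       modality = "full"), class = "point_cloud")
  rg <- structure(list(min = c(x = 0, y = 0, z = 0),
                       max = c(x = 1, y = 1, z = 1)),
                  class = "normalization_ranges")
  dm <- density_map(cl, rg, "z")
  expect_equal(which(dm$raw > 0), 51L)          # R is 1-based
  expect_equal(which.max(dm$values), 51L)
  prof <- dm$values[51 + (-5:5)]
  expect_equal(prof, rev(prof))                  # symmetric kernel
  expect_equal(sum(dm$values), 1, tolerance = 1e-9)

  # translated cloud -> translated argmax (0.725/0.012 -> 0-based bin 60)
  cl2 <- cl; cl2$points[, "z"] <- 0.625
  dm2 <- density_map(cl2, rg, "z")
  expect_equal(which.max(dm2$values), 61L)

  # determinism
  expect_identical(density_map(cl, rg, "xz")$values,
                   density_map(cl, rg, "xz")$values)
})

test_that("mass is conserved for interior clouds (1e-6 relative)", {
  pop <- small_pop(31, n = 8)
  m <- pop$morphologies[[1]]
  cl <- sample_points(m, 0.1)
  rg <- fit_ranges(cl)                           # data fit: all interior
  for (ax in c("z", "x", "xz", "yz")) {
    dm <- density_map(cl, rg, ax)
    expect_equal(sum(dm$values) / nrow(cl$points), 1, tolerance = 1e-6)
    expect_true(all(dm$values >= 0))
    expect_equal(dm$n_clipped, 0L)
  }
})

test_that("out-of-span points are clipped into boundary bins, not dropped", {
  cl <- structure(list(points = cbind(x = c(0.5, 9), y = c(0.5, 0.5),
                                      z = c(0.5, -9)), modality = "full"),
                  class = "point_cloud")
  rg <- structure(list(min = c(x = 0, y = 0, z = 0),
                       max = c(x = 1, y = 1, z = 1)),
                  class = "normalization_ranges")
  dm <- density_map(cl, rg, "z")
  expect_equal(dm$n_clipped, 1L)
  expect_equal(sum(dm$raw), 2)                   # mass kept
})

test_that("2D smoothing is separable and marginals match 1D histograms", {
  pop <- small_pop(37, n = 8)
  cl <- sample_points(pop$morphologies[[2]], 0.2)
  rg <- fit_ranges(cl)
  dm2 <- density_map(cl, rg, "xz")
  # oracle: full 2D convolution with the outer-product kernel
  k1 <- morphrep:::gaussian_kernel(11, 2)
  k2 <- outer(k1, k1)
  raw <- dm2$raw
  direct <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100) {
    acc <- 0
    for (a in -5:5) for (b in -5:5) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= 100 && jj >= 1 && jj <= 100)
        acc <- acc + k2[a + 6, b + 6] * raw[ii, jj]
    }
    direct[i, j] <- acc
  }
  expect_equal(dm2$values, direct, tolerance = 1e-9)
  # raw-histogram marginals equal the raw 1D histograms
  dmx <- density_map(cl, rg, "x")
  dmz <- density_map(cl, rg, "z")
  expect_equal(rowSums(raw), dmx$raw)
  expect_equal(colSums(raw), dmz$raw)
})
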