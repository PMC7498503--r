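test_that("mean differences behave like means", {
  la <- c(p1 = 0.3, p2 = 0.5)
  expect_equal(mean_delta(la, la), 0)
  expect_equal(mean_delta(la, la + 0.1), 0.1)
  lb <- c(p1 = 0.5, p2 = 0.4)                    # diffs 0.2 and -0.1
  expect_equal(mean_delta(la, lb), 0.05)
  expect_error(mean_delta(la, c(p1 = 0.1, p3 = 0.2)), "mismatch")
})

test_that("the jackknife-across-types SE matches hand evaluation", {
  la <- c(AB = 0, AC = 0, BC = 0)
  lb <- c(AB = 0.3, AC = 0, BC = 0)
  pt <- data.frame(pair = c("AB", "AC", "BC"),
                   type1 = c("A", "A", "B"), type2 = c("B", "C", "C"))
  jk <- jackknife_se(la, lb, pt)
  # delta_{-A} = mean({BC}) = 0; delta_{-B} = 0; delta_{-C} = mean({AB}) = 0.3
  expect_equal(unname(jk$delta_loo[c("A", "B", "C")]), c(0, 0, 0.3))
  expect_equal(jk$delta, 0.1)
  # SE = sqrt(2/3 * (0.01 + 0.01 + 0.04)) = 0.2
  expect_equal(jk$se, 0.2, tolerance = 1e-12)
  expect_length(jk$delta_loo, 3L)                # n leave-one-out values
  # swapping A and B flips every delta sign, SE unchanged
  jk2 <- jackknife_se(lb, la, pt)
  expect_equal(jk2$delta_loo, -jk$delta_loo)
  expect_equal(jk2$se, jk$se)
  # identical leave-one-out values give SE = 0
  jk3 <- jackknife_se(la, la + 0.2, pt)
  expect_equal(jk3$se, 0)
})

test_that("z-test p-values follow the normal distribution", {
  expect_equal(z_test(0, 1), list(z = 0, p = 1))
  expect_equal(z_test(1.96, 1)$p, 0.05, tolerance = 1e-3)
  zt <- z_test(0.1, 0.1)
  expect_equal(zt$z, 1)
  expect_equal(zt$p, 0.3173, tolerance = 1e-4)
  expect_warning(z_test(0.1, 0), "zero SE")
})

test_that("pooled pair counts follow K choose 2", {
  counts <- vapply(c(11, 7, 7, 6), function(K) choose(K, 2), 0)
  expect_equal(counts, c(55, 21, 21, 15))
  expect_equal(sum(counts), 112)
})

test_that("representation ranking selects dominant features", {
  reps <- c("r1", "r2", "r3")
  pairs <- paste0("p", 1:4)
  grid <- expand.grid(representation = reps, modality = c("full", "axon"),
                      pair = pairs, stringsAsFactors = FALSE)
  base <- c(r1 = 0.1, r2 = 0.4, r3 = 0.6)
  grid$log_loss <- base[grid$representation]
  rk <- rank_features(grid, distributions = "r3", top_n = 2)
  expect_equal(rk$ranking$representation[rk$ranking$modality == "full"][1],
               "r1")
  expect_true("r3" %in% rk$selected)             # best distribution included
  expect_error(rank_features(grid[-1, ], distributions = "r3"), "missing")
})

test_that("the t-SNE embedding is deterministic and separates planted types", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60), 20), matrix(rnorm(60, mean = 8), 20))
  y <- factor(rep(c("A", "B"), each = 20))
  e1 <- embed_features(x, y, perplexity = 5, seed = 42)
  e2 <- embed_features(x, y, perplexity = 5, seed = 42)
  expect_identical(e1$coords, e2$coords)
  cA <- e1$ellipses$A$center; cB <- e1$ellipses$B$center
  gap <- sqrt(sum((cA - cB)^2))
  major <- function(e) sqrt(max(eigen(e$cov)$values) * stats::qchisq(0.95, 2))
  expect_gt(gap, major(e1$ellipses$A) + major(e1$ellipses$B))
})

test_that("coverage ellipses resist single outliers", {
  set.seed(7)
  pts <- cbind(rnorm(30), rnorm(30))
  lab <- factor(rep("A", 30))
  e_clean <- coverage_ellipses(pts, lab)$A
  pts_out <- pts
  pts_out[1, ] <- c(500, 500)
  e_dirty <- coverage_ellipses(pts_out, lab)$A
  expect_lt(sqrt(sum((e_clean$center - e_dirty$center)^2)), 1)
  expect_lt(abs(det(e_dirty$cov) / det(e_clean$cov) - 1), 1)
})
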