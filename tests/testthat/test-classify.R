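make_gaussian_pair <- function(n_per = 20L, sep = 6, p = 10L, seed = 99L) {
  morphrep:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p), n_per),
               matrix(rnorm(n_per * p), n_per))
    x[seq_len(n_per), 1] <- x[seq_len(n_per), 1] + sep
    list(x = x, y = factor(rep(c("A", "B"), each = n_per)))
  })
}

test_that("PCA preprocessing retains variance and scales by PC1", {
  set.seed(1)
  base <- rnorm(30)
  rank1 <- cbind(base, 2 * base, -base)          # rank-1 data -> exactly 1 PC
  pp <- preprocess_features(rank1, method = "pca")
  expect_equal(pp$k, 1L)
  x <- matrix(rnorm(40 * 6), 40)
  te <- matrix(rnorm(5 * 6), 5)
  pp2 <- preprocess_features(x, te, method = "pca", var_fraction = 0.9)
  expect_equal(stats::sd(pp2$train[, 1]), 1, tolerance = 1e-12)
  # a test row equal to the train mean maps to the origin
  te_mean <- matrix(colMeans(x), 1)
  pp3 <- preprocess_features(x, te_mean, method = "pca")
  expect_equal(as.numeric(pp3$test), rep(0, pp3$k), tolerance = 1e-12)
  expect_error(preprocess_features(matrix(1, 5, 3), method = "pca"),
               "zero-variance")
})

test_that("combining representations concatenates columns", {
  a <- matrix(rnorm(20), 10)
  expect_equal(ncol(combine_representations(list(a, a))), 4L)
  b <- matrix(rnorm(8), 4)
  expect_error(combine_representations(list(a, b)), "row mismatch")
})

test_that("metrics reproduce their closed forms", {
  y <- factor(c("a", "b", "a", "b"))
  expect_equal(metric_log_loss(y, rep(0.5, 4)), log(2))
  expect_equal(metric("log_loss", y, rep(0.5, 4)), log(2))
  # constant 1/K multinomial prediction: ln K
  for (K in c(11L, 7L, 6L)) {
    yk <- factor(rep(paste0("t", seq_len(K)), each = 2))
    pk <- matrix(1 / K, length(yk), K,
                 dimnames = list(NULL, levels(yk)))
    expect_equal(metric_log_loss(yk, pk), log(K))
  }
  # perfect prediction
  yp <- factor(c("a", "a", "b"))
  expect_equal(metric_accuracy(yp, c("a", "a", "b")), 1)
  expect_equal(metric_macro_f1(yp, c("a", "a", "b")), 1)
  expect_equal(metric_mcc(yp, c("a", "a", "b")), 1)
  expect_lt(metric_log_loss(yp, c(1e-15, 1e-15, 1 - 1e-15)), 1e-10)
  # the 2x2 confusion table TP=40 TN=30 FP=10 FN=20
  yt <- factor(c(rep("pos", 60), rep("neg", 40)), levels = c("neg", "pos"))
  yhat <- c(rep("pos", 40), rep("neg", 20), rep("pos", 10), rep("neg", 30))
  expect_equal(metric_mcc(yt, yhat), 1000 / sqrt(50 * 60 * 40 * 50),
               tolerance = 1e-12)
  expect_equal(suppressWarnings(metric_mcc(factor(c("a", "a")), c("a", "b"))), 0)
})

test_that("well-separated clusters are classified almost perfectly", {
  gp <- make_gaussian_pair(n_per = 40L, sep = 8)
  res <- fit_binary(gp$x, gp$y, quick_config())
  expect_lt(res$means[["log_loss"]], 0.05)
  expect_equal(res$means[["accuracy"]], 1)
})

test_that("shuffled labels sit at the ln(2) chance level", {
  gp <- make_gaussian_pair(n_per = 20L, sep = 8)
  ys <- morphrep:::with_seed(5, sample(gp$y))
  res <- fit_binary(gp$x, ys, quick_config())
  expect_lt(abs(res$means[["log_loss"]] - log(2)), 0.15)
})

test_that("duplicating every sample leaves the mean metrics unchanged", {
  gp <- make_gaussian_pair(n_per = 20L, sep = 8)
  res1 <- fit_binary(gp$x, gp$y, quick_config())
  res2 <- fit_binary(gp$x[rep(seq_along(gp$y), 2), ],
                     gp$y[rep(seq_along(gp$y), 2)], quick_config())
  expect_equal(res2$means[["log_loss"]], res1$means[["log_loss"]],
               tolerance = 0.05)
  expect_equal(res2$means[["accuracy"]], res1$means[["accuracy"]],
               tolerance = 0.05)
})

test_that("multinomial classification hits ln(K) without signal, ~0 with", {
  K <- 3L; n_per <- 10L; p <- 6L
  x0 <- morphrep:::with_seed(11, matrix(rnorm(K * n_per * p), K * n_per))
  y <- factor(rep(paste0("t", 1:K), each = n_per))
  res0 <- fit_multiclass(x0, y, quick_config())
  expect_lt(abs(res0$means[["log_loss"]] - log(K)), 0.1)
  xs <- x0
  xs[, 1] <- xs[, 1] + 10 * (as.integer(y) == 2)
  xs[, 2] <- xs[, 2] + 10 * (as.integer(y) == 3)
  res1 <- fit_multiclass(xs, y, quick_config())
  expect_lt(res1$means[["log_loss"]], 0.1)
})

test_that("alternative classifiers run the same outer CV", {
  gp <- make_gaussian_pair(n_per = 15L, sep = 10)
  kn <- fit_alternative(gp$x, gp$y, "knn3", quick_config())
  expect_equal(kn$means[["accuracy"]], 1)
  expect_false("log_loss" %in% names(kn$means))
  t1 <- fit_alternative(gp$x, gp$y, "tree", quick_config())
  t2 <- fit_alternative(gp$x, gp$y, "tree", quick_config())
  expect_identical(t1$per_fold, t2$per_fold)      # seeded determinism
  ys <- morphrep:::with_seed(3, sample(gp$y))
  kn0 <- fit_alternative(gp$x, ys, "knn3", quick_config())
  expect_lt(abs(kn0$means[["accuracy"]] - 0.5), 0.2)
})

test_that("fold assignments are stratified, seeded and leakage-free", {
  y <- factor(rep(c("A", "B"), each = 12))
  f1 <- stratified_folds(y, 5, 10, 17)
  f2 <- stratified_folds(y, 5, 10, 17)
  expect_identical(f1, f2)                        # bit-identical under seed 17
  for (r in 1:10) for (k in 1:5)
    expect_true(all(table(y[f1[, r] == k]) >= 1))
  # preprocessing is fitted on training rows only: permuting the test rows
  # permutes the outputs but never changes the fitted transform
  x <- matrix(rnorm(24 * 5), 24)
  tr <- 1:16; te <- 17:24
  pp_a <- preprocess_features(x[tr, ], x[te, ])
  perm <- sample(length(te))
  pp_b <- preprocess_features(x[tr, ], x[te[perm], ])
  expect_identical(pp_a$train, pp_b$train)
  expect_equal(pp_a$test[perm, ], pp_b$test)
})
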