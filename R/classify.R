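# Supervised benchmark: PCA/scaling preprocessing, elastic-net logistic
# regression with nested cross-validation, alternative classifiers, metrics.

#' Cross-validation configuration for the benchmark
#'
#' Defaults follow the standardized pipeline: 10 times repeated stratified
#' 5-fold outer cross-validation seeded with 17, 3-fold inner
#' cross-validation for the regularization path, elastic-net mixing
#' parameter alpha = 0.5 with the one-standard-error lambda rule, and PCA
#' preprocessing keeping 90\% of the training variance.
#'
#' @param outer_folds,outer_repeats outer CV geometry.
#' @param inner_folds inner CV folds for lambda selection.
#' @param alpha elastic-net mixing parameter.
#' @param var_fraction PCA variance fraction retained.
#' @param seed RNG seed for all fold assignments.
#' @param nlambda,lambda_min_ratio regularization path geometry.
#' @return A list of class \code{cv_config}.
#' @export
cv_config <- function(outer_folds = 5L, outer_repeats = 10L, inner_folds = 3L,
                      alpha = 0.5, var_fraction = 0.9, seed = 17L,
                      nlambda = 100L, lambda_min_ratio = 1e-3) {
  stopifnot(outer_folds >= 2L, inner_folds >= 2L,
            var_fraction > 0, var_fraction <= 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 outer_repeats = as.integer(outer_repeats),
                 inner_folds = as.integer(inner_folds), alpha = alpha,
                 var_fraction = var_fraction, seed = as.integer(seed),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "cv_config")
}

#' Stratified repeated k-fold assignments
#'
#' Deterministic given the seed: within each class, indices are shuffled and
#' dealt round-robin into folds, so every fold contains every class whenever
#' the class has at least k members.
#'
#' @param y class labels.
#' @param k folds.
#' @param repeats repeats.
#' @param seed RNG seed.
#' @return An integer matrix, \code{length(y)} rows x \code{repeats} columns.
#' @export
stratified_folds <- function(y, k, repeats, seed) {
  y <- as.factor(y)
  n <- length(y)
  with_seed(seed, {
    out <- matrix(NA_integer_, n, repeats)
    for (r in seq_len(repeats)) {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        out[idx, r] <- (seq_along(idx) - 1L) %% k + 1L
      }
    }
    out
  })
}

#' Fold-wise feature preprocessing
#'
#' Fitted strictly on the training rows and applied to the test rows.
#' \code{method = "pca"}: center on the training mean, project onto the
#' smallest number of principal components capturing at least
#' \code{var_fraction} of the training variance, then divide every component
#' by the standard deviation of the training PC1 scores.
#' \code{method = "zscore"}: column-wise z-scoring with training moments
#' (used for the 24 morphometric statistics when analysed on their own).
#'
#' @param train,test numeric matrices with aligned columns.
#' @param method "pca" or "zscore".
#' @param var_fraction PCA variance fraction.
#' @return list(train, test, k = retained dimensions).
#' @export
preprocess_features <- function(train, test = NULL,
                                method = c("pca", "zscore"),
                                var_fraction = 0.9) {
  method <- match.arg(method)
  train <- as.matrix(train)
  if (!is.null(test)) test <- as.matrix(test)
  if (method == "zscore") {
    mu <- colMeans(train)
    sdv <- apply(train, 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    tr <- sweep(sweep(train, 2, mu), 2, sdv, "/")
    te <- if (is.null(test)) NULL else sweep(sweep(test, 2, mu), 2, sdv, "/")
    return(list(train = tr, test = te, k = ncol(train)))
  }
  mu <- colMeans(train)
  ctr <- sweep(train, 2, mu)
  sv <- svd(ctr, nu = 0)
  ev <- sv$d^2
  if (sum(ev) <= 0) stop("zero-variance training matrix")
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= var_fraction - 1e-12)[1]
  rot <- sv$v[, seq_len(k), drop = FALSE]
  scores <- ctr %*% rot
  s1 <- stats::sd(scores[, 1])
  if (s1 == 0) s1 <- 1
  tr <- scores / s1
  te <- if (is.null(test)) NULL else (sweep(test, 2, mu) %*% rot) / s1
  list(train = tr, test = te, k = k)
}

#' Combine preprocessed feature representations
#'
#' Column-concatenates representations that were already PCA-reduced and
#' PC1-scaled, putting them roughly on a common scale.
#'
#' @param reps list of numeric matrices with equal row counts.
#' @return A combined matrix.
#' @export
combine_representations <- function(reps) {
  n <- unique(vapply(reps, nrow, 0L))
  if (length(n) != 1L) stop("row mismatch between representations")
  do.call(cbind, reps)
}

# ---- metrics -----------------------------------------------------------

clip_prob <- function(p, eps = 1e-15) pmin(pmax(p, eps), 1 - eps)

#' Classification performance metrics
#'
#' \code{metric_log_loss} takes class probabilities (a vector of
#' second-level probabilities for binary problems, or an n x K matrix with
#' level-named columns), clipped away from 0/1 by 1e-15.
#' \code{metric_macro_f1} is the unweighted mean of per-class F1 scores.
#' \code{metric_mcc} is the Matthews correlation coefficient (the multiclass
#' generalization for K > 2); degenerate single-class folds score 0 with a
#' warning.
#'
#' @param y_true true labels (factor).
#' @param prob probabilities (log-loss).
#' @param y_pred predicted labels (other metrics).
#' @return A scalar.
#' @export
metric_log_loss <- function(y_true, prob) {
  y_true <- as.factor(y_true)
  if (is.matrix(prob)) {
    p <- clip_prob(prob[cbind(seq_along(y_true),
                              match(y_true, colnames(prob)))])
  } else {
    stopifnot(nlevels(y_true) <= 2L)
    p2 <- clip_prob(prob)
    p <- ifelse(y_true == levels(y_true)[length(levels(y_true))], p2, 1 - p2)
  }
  -mean(log(p))
}

#' @rdname metric_log_loss
#' @export
metric_accuracy <- function(y_true, y_pred) mean(as.character(y_true) == as.character(y_pred))

#' @rdname metric_log_loss
#' @export
metric_macro_f1 <- function(y_true, y_pred) {
  lev <- levels(as.factor(y_true))
  f1 <- vapply(lev, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

#' @rdname metric_log_loss
#' @export
metric_mcc <- function(y_true, y_pred) {
  lev <- unique(c(as.character(y_true), as.character(y_pred)))
  if (length(unique(as.character(y_true))) < 2L) {
    warning("single-class truth; MCC recorded as 0", call. = FALSE)
    return(0)
  }
  cm <- table(factor(y_true, levels = lev), factor(y_pred, levels = lev))
  s <- sum(cm)
  c0 <- sum(diag(cm))
  t_k <- rowSums(cm)   # truth counts
  p_k <- colSums(cm)   # prediction counts
  num <- c0 * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' @rdname metric_log_loss
#' @param name one of "log_loss", "accuracy", "macro_f1", "mcc".
#' @param y_pred_or_prob probabilities for log-loss, else predicted labels
#'   (a probability input is converted by argmax / 0.5 threshold).
#' @export
metric <- function(name = c("log_loss", "accuracy", "macro_f1", "mcc"),
                   y_true, y_pred_or_prob) {
  name <- match.arg(name)
  if (name == "log_loss") return(metric_log_loss(y_true, y_pred_or_prob))
  y_pred <- y_pred_or_prob
  if (is.matrix(y_pred)) y_pred <- colnames(y_pred)[max.col(y_pred)]
  else if (is.numeric(y_pred)) {
    lev <- levels(as.factor(y_true))
    y_pred <- lev[(y_pred > 0.5) + 1L]
  }
  switch(name,
         accuracy = metric_accuracy(y_true, y_pred),
         macro_f1 = metric_macro_f1(y_true, y_pred),
         mcc = metric_mcc(y_true, y_pred))
}

# ---- elastic-net nested CV ---------------------------------------------

# Preprocess a (possibly multi-representation) feature input inside a fold.
# x: matrix or named list of matrices; preprocess: "pca"/"zscore" or a
# vector matching the list.
fold_features <- function(x, train_idx, test_idx, preprocess, var_fraction) {
  if (!is.list(x)) x <- list(x)
  if (length(preprocess) == 1L) preprocess <- rep(preprocess, length(x))
  parts_tr <- list(); parts_te <- list(); ks <- integer(0)
  for (i in seq_along(x)) {
    pp <- preprocess_features(x[[i]][train_idx, , drop = FALSE],
                              x[[i]][test_idx, , drop = FALSE],
                              method = preprocess[i],
                              var_fraction = var_fraction)
    parts_tr[[i]] <- pp$train; parts_te[[i]] <- pp$test
    ks[i] <- pp$k
  }
  list(train = combine_representations(parts_tr),
       test = combine_representations(parts_te), k = sum(ks))
}

pad_two_cols <- function(m) {
  if (ncol(m) >= 2L) m else cbind(m, 0)
}

glmnet_fold <- function(xtr, ytr, xte, config, family, fold_seed) {
  foldid <- stratified_folds(ytr, config$inner_folds, 1L, fold_seed)[, 1]
  # glmnet emits advisory warnings for the small per-class counts that are
  # routine in this benchmark; they carry no information here
  fit <- withCallingHandlers(
    glmnet::cv.glmnet(pad_two_cols(xtr), ytr, family = family,
                      alpha = config$alpha,
                      nlambda = config$nlambda,
                      lambda.min.ratio = config$lambda_min_ratio,
                      standardize = FALSE, foldid = foldid,
                      type.measure = "deviance"),
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations|grouped=FALSE", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  stats::predict(fit, newx = pad_two_cols(xte), s = "lambda.1se",
                 type = "response")
}

#' Pairwise elastic-net classification benchmark
#'
#' For one pair of cell types: repeated stratified outer cross-validation;
#' within each outer training fold the features are preprocessed (PCA /
#' z-scoring fitted on the fold's training rows only), an elastic-net
#' logistic regression is fitted over a log-spaced lambda path with the
#' mixing parameter from \code{config}, lambda is chosen by the
#' one-standard-error rule on inner k-fold cross-validated log-loss, and
#' test-fold log-loss, accuracy, macro-F1 and MCC are recorded.
#'
#' @param x feature matrix (cells x features), or a named list of matrices
#'   for combined representations (each preprocessed separately, then
#'   concatenated).
#' @param y two-level factor of cell-type labels.
#' @param config a \code{\link{cv_config}}.
#' @param preprocess "pca" or "zscore" (vector-valued for lists; morphometric
#'   statistics used inside a combination are PCA-reduced like the rest).
#' @return An object of class \code{pair_result} with per-fold metrics and
#'   their means.
#' @export
fit_binary <- function(x, y, config = cv_config(), preprocess = "pca") {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("fit_binary needs exactly 2 classes")
  if (any(table(y) < config$outer_folds))
    stop("every class needs at least ", config$outer_folds, " cells")
  folds <- stratified_folds(y, config$outer_folds, config$outer_repeats,
                            config$seed)
  rows <- list()
  fold_counter <- 0L
  for (r in seq_len(config$outer_repeats)) {
    for (kf in seq_len(config$outer_folds)) {
      fold_counter <- fold_counter + 1L
      te <- which(folds[, r] == kf)
      tr <- which(folds[, r] != kf)
      ff <- fold_features(x, tr, te, preprocess, config$var_fraction)
      prob <- glmnet_fold(ff$train, y[tr], ff$test, config, "binomial",
                          derive_seed(config$seed, fold_counter))
      prob <- as.numeric(prob)
      pred <- levels(y)[(prob > 0.5) + 1L]
      rows[[fold_counter]] <- data.frame(
        rep = r, fold = kf, n_test = length(te), k_features = ff$k,
        log_loss = metric_log_loss(y[te], prob),
        accuracy = metric_accuracy(y[te], pred),
        macro_f1 = metric_macro_f1(y[te], pred),
        mcc = metric_mcc(y[te], pred))
    }
  }
  per_fold <- do.call(rbind, rows)
  res <- list(pair = levels(y), per_fold = per_fold,
              means = colMeans(per_fold[, c("log_loss", "accuracy",
                                            "macro_f1", "mcc")]),
              config = config, scheme = "logreg")
  class(res) <- "pair_result"
  res
}

#' Multinomial elastic-net classification benchmark
#'
#' Same nested cross-validation pipeline as \code{\link{fit_binary}} with a
#' multinomial loss; chance level is ln(K) for K balanced classes.
#'
#' @inheritParams fit_binary
#' @return An object of class \code{multi_result}.
#' @export
fit_multiclass <- function(x, y, config = cv_config(), preprocess = "pca") {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 3L) stop("fit_multiclass needs 3 or more classes")
  if (any(table(y) < config$outer_folds))
    stop("every class needs at least ", config$outer_folds, " cells")
  folds <- stratified_folds(y, config$outer_folds, config$outer_repeats,
                            config$seed)
  rows <- list()
  fold_counter <- 0L
  for (r in seq_len(config$outer_repeats)) {
    for (kf in seq_len(config$outer_folds)) {
      fold_counter <- fold_counter + 1L
      te <- which(folds[, r] == kf)
      tr <- which(folds[, r] != kf)
      ff <- fold_features(x, tr, te, preprocess, config$var_fraction)
      prob <- glmnet_fold(ff$train, y[tr], ff$test, config, "multinomial",
                          derive_seed(config$seed, fold_counter))
      prob <- matrix(prob, nrow = length(te),
                     dimnames = list(NULL, dimnames(prob)[[2]]))
      pred <- colnames(prob)[max.col(prob)]
      rows[[fold_counter]] <- data.frame(
        rep = r, fold = kf, n_test = length(te), k_features = ff$k,
        log_loss = metric_log_loss(y[te], prob),
        accuracy = metric_accuracy(y[te], pred),
        macro_f1 = metric_macro_f1(y[te], pred),
        mcc = metric_mcc(y[te], pred))
    }
  }
  per_fold <- do.call(rbind, rows)
  res <- list(classes = levels(y), per_fold = per_fold,
              means = colMeans(per_fold[, c("log_loss", "accuracy",
                                            "macro_f1", "mcc")]),
              chance = log(nlevels(y)), config = config, scheme = "logreg")
  class(res) <- c("multi_result", "pair_result")
  res
}

#' Alternative pairwise classifiers
#'
#' Runs the identical outer cross-validation with a 3-nearest-neighbour or a
#' decision-tree classifier; log-loss is not meaningful for these schemes, so
#' only accuracy, macro-F1 and MCC are reported.
#'
#' @inheritParams fit_binary
#' @param scheme "knn3" or "tree".
#' @return A \code{pair_result} (without log-loss).
#' @export
fit_alternative <- function(x, y, scheme = c("knn3", "tree"),
                            config = cv_config(), preprocess = "pca") {
  scheme <- match.arg(scheme)
  y <- droplevels(as.factor(y))
  if (any(table(y) < config$outer_folds))
    stop("every class needs at least ", config$outer_folds, " cells")
  folds <- stratified_folds(y, config$outer_folds, config$outer_repeats,
                            config$seed)
  rows <- list()
  fold_counter <- 0L
  for (r in seq_len(config$outer_repeats)) {
    for (kf in seq_len(config$outer_folds)) {
      fold_counter <- fold_counter + 1L
      te <- which(folds[, r] == kf)
      tr <- which(folds[, r] != kf)
      ff <- fold_features(x, tr, te, preprocess, config$var_fraction)
      if (scheme == "knn3") {
        pred <- as.character(class::knn(ff$train, ff$test, y[tr], k = 3))
      } else {
        df_tr <- data.frame(.y = y[tr], ff$train)
        df_te <- data.frame(ff$test)
        colnames(df_te) <- colnames(df_tr)[-1]
        fit <- with_seed(config$seed,
          rpart::rpart(.y ~ ., data = df_tr, method = "class"))
        pred <- as.character(stats::predict(fit, df_te, type = "class"))
      }
      rows[[fold_counter]] <- data.frame(
        rep = r, fold = kf, n_test = length(te), k_features = ff$k,
        accuracy = metric_accuracy(y[te], pred),
        macro_f1 = metric_macro_f1(y[te], pred),
        mcc = metric_mcc(y[te], pred))
    }
  }
  per_fold <- do.call(rbind, rows)
  res <- list(pair = levels(y), per_fold = per_fold,
              means = colMeans(per_fold[, c("accuracy", "macro_f1", "mcc")]),
              config = config, scheme = scheme)
  class(res) <- "pair_result"
  res
}

#' @export
print.pair_result <- function(x, ...) {
  hdr <- if (!is.null(x$classes))
    paste0("Multinomial benchmark (", length(x$classes), " classes, ",
           x$scheme, ")")
  else paste0("Pairwise benchmark ", paste(x$pair, collapse = " vs "),
              " (", x$scheme, ")")
  cat(hdr, "\n")
  m <- x$means
  cat(paste(sprintf("%s %.4f", names(m), m), collapse = " | "), "\n")
  if (!is.null(x$chance)) cat(sprintf("chance log-loss ln(K) = %.4f\n", x$chance))
  cat(sprintf("(%d outer folds: %d folds x %d repeats)\n", nrow(x$per_fold),
              x$config$outer_folds, x$config$outer_repeats))
  invisible(x)
}

#' @export
summary.pair_result <- function(object, ...) {
  sds <- apply(object$per_fold[, names(object$means), drop = FALSE], 2,
               stats::sd)
  out <- data.frame(metric = names(object$means), mean = as.numeric(object$means),
                    sd = as.numeric(sds))
  out
}
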