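# Representation comparison: mean log-loss differences with a
# jackknife-across-types standard error, representation ranking, and the
# exact t-SNE embedding with robust coverage ellipses.

#' Mean log-loss difference between two representations
#'
#' \eqn{\delta(A,B)} is the mean of \eqn{\ell(B,p) - \ell(A,p)} over the set
#' of cell-type pairs p (pooled across datasets). Positive values mean A
#' performs better (lower loss).
#'
#' @param loss_a,loss_b named numeric vectors of per-pair log-losses with
#'   identical pair names.
#' @return A scalar.
#' @export
mean_delta <- function(loss_a, loss_b) {
  if (is.null(names(loss_a)) || is.null(names(loss_b)) ||
      !setequal(names(loss_a), names(loss_b)) ||
      length(loss_a) != length(loss_b))
    stop("pair coverage mismatch between the two result sets")
  loss_b <- loss_b[names(loss_a)]
  mean(loss_b - loss_a)
}

#' Jackknife-across-types standard error of a mean difference
#'
#' Per-pair log-losses are not independent because pairs share cells of the
#' same type, so the usual standard error of \eqn{\delta(A,B)} is invalid.
#' Instead one type \eqn{\tau} is left out entirely (removing every pair that
#' involves it), giving leave-one-type-out estimates \eqn{\delta_{-\tau}};
#' the jackknife standard error is
#' \deqn{\widehat{SE} = [ (n-1)/n \sum_\tau (\delta_{-\tau} - \bar\delta)^2 ]^{1/2}}
#' with n the number of types and \eqn{\bar\delta} the mean of the
#' \eqn{\delta_{-\tau}}.
#'
#' @param loss_a,loss_b named per-pair log-loss vectors.
#' @param pair_types data.frame with columns \code{pair} (matching the names
#'   of the loss vectors), \code{type1}, \code{type2}. Types must be unique
#'   across datasets (prefix them with the dataset id when pooling).
#' @return list(delta, se, delta_loo (named by left-out type)).
#' @export
jackknife_se <- function(loss_a, loss_b, pair_types) {
  stopifnot(all(c("pair", "type1", "type2") %in% names(pair_types)))
  if (!setequal(pair_types$pair, names(loss_a)))
    stop("pair coverage mismatch between losses and pair_types")
  types <- sort(unique(c(as.character(pair_types$type1),
                         as.character(pair_types$type2))))
  if (length(types) < 3L) stop("jackknife across types needs >= 3 types")
  diffs <- (loss_b - loss_a)[pair_types$pair]
  delta <- mean(diffs)
  loo <- vapply(types, function(tau) {
    keep <- pair_types$type1 != tau & pair_types$type2 != tau
    if (!any(keep))
      stop("removing type ", tau, " leaves no pairs")
    mean(diffs[keep])
  }, 0)
  n <- length(types)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  list(delta = delta, se = se, delta_loo = loo)
}

#' z-test for a representation difference
#'
#' @param delta mean difference from \code{\link{mean_delta}}.
#' @param se jackknife standard error.
#' @return list(z, p) with the two-sided normal p-value.
#' @export
z_test <- function(delta, se) {
  if (se < 0) stop("negative SE")
  if (se == 0) {
    if (delta == 0) return(list(z = 0, p = 1))
    warning("zero SE with nonzero delta; p = 0", call. = FALSE)
    return(list(z = sign(delta) * Inf, p = 0))
  }
  z <- delta / se
  list(z = z, p = 2 * (1 - stats::pnorm(abs(z))))
}

#' Compare two representations end to end
#'
#' Convenience wrapper returning \eqn{\delta}, jackknife SE, z and the
#' two-sided p-value as a classed object.
#'
#' @inheritParams jackknife_se
#' @param name_a,name_b representation labels for printing.
#' @return An object of class \code{delta_comparison}.
#' @export
compare_representations <- function(loss_a, loss_b, pair_types,
                                    name_a = "A", name_b = "B") {
  jk <- jackknife_se(loss_a, loss_b, pair_types)
  zt <- z_test(jk$delta, jk$se)
  structure(c(jk, zt, list(name_a = name_a, name_b = name_b)),
            class = "delta_comparison")
}

#' @export
print.delta_comparison <- function(x, ...) {
  cat(sprintf("delta(%s, %s) = %.4f +- %.4f (jackknife SE, %d types)\n",
              x$name_a, x$name_b, x$delta, x$se, length(x$delta_loo)))
  cat(sprintf("z = %.3f, two-sided p = %.4g\n", x$z, x$p))
  invisible(x)
}

#' Rank feature representations and select the top set
#'
#' Ranks representations by their mean pairwise log-loss (pooled over all
#' pairs) within each modality and forms the selected set: the union of the
#' per-modality top five plus the best-performing morphometric distribution,
#' so every representation category is covered.
#'
#' @param results data.frame with columns \code{representation},
#'   \code{modality}, \code{pair}, \code{log_loss}.
#' @param distributions character vector naming which representations are
#'   morphometric distributions.
#' @param top_n per-modality depth of the selection, default 5.
#' @return list(ranking = data.frame ordered by mean loss within modality,
#'   selected = character vector).
#' @export
rank_features <- function(results, distributions = character(0), top_n = 5L) {
  need <- c("representation", "modality", "pair", "log_loss")
  stopifnot(all(need %in% names(results)))
  full <- expand.grid(representation = unique(results$representation),
                      modality = unique(results$modality),
                      pair = unique(results$pair), stringsAsFactors = FALSE)
  key <- function(d) paste(d$representation, d$modality, d$pair, sep = "\r")
  missing <- setdiff(key(full), key(results))
  if (length(missing))
    stop("missing result cells: ",
         paste(utils::head(gsub("\r", " / ", missing), 5), collapse = "; "),
         if (length(missing) > 5) " ...")
  agg <- stats::aggregate(log_loss ~ representation + modality, results, mean)
  agg <- agg[order(agg$modality, agg$log_loss), ]
  sel <- unlist(lapply(split(agg, agg$modality), function(d)
    utils::head(d$representation, top_n)))
  selected <- unique(sel)
  if (length(distributions)) {
    dist_agg <- stats::aggregate(
      log_loss ~ representation,
      results[results$representation %in% distributions, , drop = FALSE],
      mean)
    if (nrow(dist_agg)) {
      best_dist <- dist_agg$representation[which.min(dist_agg$log_loss)]
      selected <- unique(c(selected, best_dist))
    }
  }
  rownames(agg) <- NULL
  list(ranking = agg, selected = selected)
}

# ---- exact t-SNE -------------------------------------------------------

# Conditional probabilities with per-point bandwidth calibrated to the
# target perplexity by bisection on log(beta).
tsne_probabilities <- function(D2, perplexity) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    Di <- D2[i, -i]
    for (iter in 1:64) {
      ex <- exp(-Di * beta)
      s <- sum(ex)
      if (s <= 0) { H <- 0 } else {
        Pi <- ex / s
        H <- -sum(Pi[Pi > 0] * log(Pi[Pi > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- ex / s
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Exact t-SNE embedding of combined feature representations
#'
#' Non-approximate t-SNE with random (seeded) initialization. Inputs should
#' already be PCA-reduced and PC1-scaled per representation and concatenated
#' (see \code{\link{preprocess_features}} and
#' \code{\link{combine_representations}}). The perplexity is capped at
#' (n - 1) / 3 for small samples. Per-type 95\% coverage ellipses use the
#' minimum covariance determinant estimator of location and scatter, so a
#' single outlying cell does not inflate them; types with fewer than 3 cells
#' get no ellipse.
#'
#' @param x numeric matrix (cells x features).
#' @param labels optional cell-type factor for the coverage ellipses.
#' @param perplexity t-SNE perplexity, default 50.
#' @param seed RNG seed for the initialization.
#' @param n_iter gradient-descent iterations, default 1000.
#' @return An object of class \code{morph_embedding}: list with \code{coords}
#'   (n x 2), \code{labels} and \code{ellipses} (per-type list with center,
#'   cov, and a 95\% ellipse path).
#' @export
embed_features <- function(x, labels = NULL, perplexity = 50, seed = 42L,
                           n_iter = 1000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 cells to embed")
  perplexity <- min(perplexity, (n - 1) / 3)
  sum_x <- rowSums(x^2)
  D2 <- pmax(outer(sum_x, sum_x, "+") - 2 * tcrossprod(x), 0)
  P <- tsne_probabilities(D2, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 200
  for (it in seq_len(n_iter)) {
    exagg <- if (it <= 100L) 12 else 1
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (exagg * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250L) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- mom * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  ellipses <- if (is.null(labels)) NULL else {
    labels <- as.factor(labels)
    coverage_ellipses(Y, labels)
  }
  structure(list(coords = Y, labels = labels, ellipses = ellipses,
                 perplexity = perplexity, seed = seed),
            class = "morph_embedding")
}

#' Robust 95\% coverage ellipses per cell type
#'
#' Location and scatter are estimated with the minimum covariance determinant
#' estimator, so a single outlying cell does not inflate an ellipse; the
#' radius uses the chi-squared(2) 95\% quantile under a Gaussian assumption.
#' Types with fewer than 3 cells get \code{NULL}.
#'
#' @param coords n x 2 coordinate matrix (e.g. a t-SNE embedding).
#' @param labels factor of cell types.
#' @param level coverage level, default 0.95.
#' @return Named list per type: list(center, cov, path) or NULL.
#' @export
coverage_ellipses <- function(coords, labels, level = 0.95) {
  labels <- as.factor(labels)
  out <- lapply(levels(labels), function(cl) {
    pts <- coords[labels == cl, , drop = FALSE]
    if (nrow(pts) < 3L) return(NULL)
    rob <- tryCatch(suppressWarnings(MASS::cov.mcd(pts)),
                    error = function(e) NULL)
    if (is.null(rob)) return(NULL)
    r <- sqrt(stats::qchisq(level, df = 2))
    eig <- eigen(rob$cov, symmetric = TRUE)
    theta <- seq(0, 2 * pi, length.out = 100)
    circ <- cbind(cos(theta), sin(theta))
    path <- t(rob$center + t(circ %*% diag(sqrt(pmax(eig$values, 0)) * r) %*%
                               t(eig$vectors)))
    list(center = rob$center, cov = rob$cov, path = path)
  })
  names(out) <- levels(labels)
  out
}

#' @export
print.morph_embedding <- function(x, ...) {
  cat("t-SNE embedding of", nrow(x$coords), "cells (perplexity",
      format(x$perplexity, digits = 4), ")\n")
  invisible(x)
}

#' @export
plot.morph_embedding <- function(x, ...) {
  lab <- x$labels %||% factor(rep("all", nrow(x$coords)))
  cols <- grDevices::hcl.colors(max(3L, nlevels(lab)), "Dark 3")
  graphics::plot(x$coords, col = cols[as.integer(lab)], pch = 16,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  if (!is.null(x$ellipses)) {
    for (i in seq_along(x$ellipses)) {
      e <- x$ellipses[[i]]
      if (!is.null(e)) graphics::lines(e$path, col = cols[i])
    }
  }
  if (nlevels(lab) > 1L)
    graphics::legend("topright", legend = levels(lab), col = cols[seq_len(nlevels(lab))],
                     pch = 16, cex = 0.7)
  invisible(x)
}
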