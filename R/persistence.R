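# Topological persistence of neurite trees: diagrams under four filter
# functions and their 1D/2D Gaussian persistence images.

persistence_filters <- c("radial_distance", "path_length", "branch_order",
                         "z_projection")

filter_values <- function(m, filter) {
  ts <- tree_structure(m)
  nd <- m$nodes
  s <- ts$root
  switch(filter,
    radial_distance = sqrt((nd$x - nd$x[s])^2 + (nd$y - nd$y[s])^2 +
                           (nd$z - nd$z[s])^2),
    path_length = {
      el <- edge_lengths(m, ts)
      d <- numeric(nrow(nd))
      for (v in seq_len(nrow(nd)))
        if (!is.na(ts$parent_row[v])) d[v] <- d[ts$parent_row[v]] + el[v]
      d
    },
    branch_order = {
      is_bp <- ts$n_children >= 2L
      is_bp[s] <- FALSE
      o <- integer(nrow(nd))
      for (v in seq_len(nrow(nd))) {
        p <- ts$parent_row[v]
        if (!is.na(p)) o[v] <- o[p] + as.integer(is_bp[p])
      }
      as.numeric(o)
    },
    z_projection = nd$z - nd$z[s],
    stop("unknown filter: ", filter)
  )
}

#' Persistence diagram of a neurite tree
#'
#' Runs the elder rule on the tree under a filter function: the birth time of
#' each branch is the filter value of its tip; sweeping from the tips toward
#' the soma, at each branch point every branch except the one with the
#' maximal birth dies, with death time equal to the branch point's filter
#' value (ties survive by the smaller tip id). The overall survivor dies at
#' the soma with death 0. The diagram has exactly one (birth, death) pair
#' per tip.
#'
#' @param m a preprocessed \code{morphology}.
#' @param filter one of "radial_distance", "path_length", "branch_order",
#'   "z_projection".
#' @param modality "full", "axon" or "dendrite".
#' @return An object of class \code{persistence_diagram}: a data.frame with
#'   columns birth, death, tip_id, plus attributes filter and modality.
#' @export
compute_diagram <- function(m, filter = c("radial_distance", "path_length",
                                          "branch_order", "z_projection"),
                            modality = c("full", "axon", "dendrite")) {
  filter <- match.arg(filter)
  modality <- match.arg(modality)
  m <- modality_subtree(m, modality)
  f <- filter_values(m, filter)
  ts <- tree_structure(m)
  nd <- m$nodes
  n <- nrow(nd)
  pairs <- list()
  # surviving branch per node, filled tips-to-soma (reverse topological order)
  surv_birth <- rep(NA_real_, n)
  surv_tip <- rep(NA_integer_, n)
  for (v in rev(seq_len(n))) {
    kids <- ts$children[[v]]
    if (!length(kids)) {
      surv_birth[v] <- f[v]
      surv_tip[v] <- nd$id[v]
      next
    }
    births <- surv_birth[kids]
    tips <- surv_tip[kids]
    win <- order(-births, tips)[1L]
    losers <- setdiff(seq_along(kids), win)
    for (l in losers)
      pairs[[length(pairs) + 1L]] <- c(births[l], f[v], tips[l])
    surv_birth[v] <- births[win]
    surv_tip[v] <- tips[win]
  }
  root <- ts$root
  pairs[[length(pairs) + 1L]] <- c(surv_birth[root], f[root], surv_tip[root])
  d <- do.call(rbind, pairs)
  out <- data.frame(birth = d[, 1], death = d[, 2], tip_id = as.integer(d[, 3]))
  structure(out, class = c("persistence_diagram", "data.frame"),
            filter = filter, modality = modality)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat("Persistence diagram (", attr(x, "filter"), ", ", attr(x, "modality"),
      "): ", nrow(x), " branches\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# Scott's-rule multivariate normal KDE evaluated on a grid; isotropic
# fixed-bandwidth fallback when the sample covariance is unusable.
kde2_grid <- function(pts, gx, gy, fallback_bw) {
  n <- nrow(pts)
  use_fallback <- n < 3L
  H <- NULL
  if (!use_fallback) {
    S <- stats::cov(pts)
    H <- S * n^(-1 / 3)                        # Scott factor^2, d = 2
    if (!all(is.finite(H)) || det(H) <= 1e-300) use_fallback <- TRUE
  }
  if (use_fallback) H <- diag(fallback_bw^2, 2L)
  Hi <- solve(H)
  dethalf <- sqrt(det(H))
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  vals <- numeric(nrow(grid))
  for (i in seq_len(n)) {
    dx <- grid[, 1] - pts[i, 1]
    dy <- grid[, 2] - pts[i, 2]
    q <- Hi[1, 1] * dx^2 + 2 * Hi[1, 2] * dx * dy + Hi[2, 2] * dy^2
    vals <- vals + exp(-q / 2)
  }
  vals <- vals / (n * 2 * pi * dethalf)
  matrix(vals, nrow = length(gx))               # [birth, death]
}

#' Two-dimensional Gaussian persistence image
#'
#' Kernel density estimate of the (birth, death) point cloud with a 2D
#' Gaussian kernel (Scott's rule on the full sample covariance), evaluated on
#' a 100 x 100 equidistant grid spanning [0, max_birth] x [0, max_death],
#' where the maxima are dataset-level constants. Diagrams with fewer than 3
#' points or a singular covariance fall back to an isotropic kernel with
#' bandwidth 1\% of max_birth.
#'
#' @param d a \code{persistence_diagram}.
#' @param max_birth,max_death dataset-level grid maxima (> 0).
#' @param grid_size grid points per axis, default 100.
#' @return An object of class \code{persistence_image}: list with the
#'   \code{values} matrix (birth x death) and the grid definition.
#' @export
persistence_image_2d <- function(d, max_birth, max_death, grid_size = 100L) {
  stopifnot(max_birth > 0, max_death > 0)
  gx <- seq(0, max_birth, length.out = grid_size)
  gy <- seq(0, max_death, length.out = grid_size)
  pts <- cbind(d$birth, d$death)
  values <- kde2_grid(pts, gx, gy, fallback_bw = 0.01 * max_birth)
  structure(list(values = values, birth_grid = gx, death_grid = gy),
            class = "persistence_image")
}

#' One-dimensional Gaussian persistence vector
#'
#' Gaussian kernel density estimate of the branch lifetimes (birth - death;
#' negative lifetimes, possible under the radial-distance and z-projection
#' filters, are clipped to 0), sampled at 100 equidistant points spanning
#' [0, max_birth]. Scott's rule bandwidth with a fixed-bandwidth fallback
#' (1\% of max_birth) for degenerate lifetime sets.
#'
#' @param d a \code{persistence_diagram}.
#' @param max_birth dataset-level maximum (> 0).
#' @param n_points sample points, default 100.
#' @return A numeric vector of length \code{n_points}.
#' @export
persistence_image_1d <- function(d, max_birth, n_points = 100L) {
  stopifnot(max_birth > 0)
  life <- d$birth - d$death
  if (any(life < 0)) {
    message(sum(life < 0), " negative lifetime(s) clipped to 0")
    life[life < 0] <- 0
  }
  n <- length(life)
  s <- stats::sd(life)
  bw <- if (n >= 2 && is.finite(s) && s > 0) s * n^(-1 / 5) else 0.01 * max_birth
  at <- seq(0, max_birth, length.out = n_points)
  vals <- vapply(at, function(t0) mean(stats::dnorm(t0, mean = life, sd = bw)), 0)
  vals
}

#' Flatten a 2D persistence image to a 10,000-feature vector (row-major)
#' @param img a \code{persistence_image}.
#' @return A numeric vector.
#' @export
flatten_persistence_image <- function(img) as.vector(t(img$values))

#' @export
print.persistence_image <- function(x, ...) {
  cat("Persistence image: ", nrow(x$values), " x ", ncol(x$values),
      " grid over [0, ", format(max(x$birth_grid), digits = 4), "] x [0, ",
      format(max(x$death_grid), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.persistence_image <- function(x, ...) {
  graphics::image(x$birth_grid, x$death_grid, x$values,
                  xlab = "birth", ylab = "death",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
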