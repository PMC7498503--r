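# Neurite density maps: dense skeleton sampling, dataset-level min-max
# normalization, fixed binning over [-0.1, 1.1], Gaussian smoothing.

#' Sample points densely along the neurites
#'
#' Places equidistant points along every sub-segment of the skeleton
#' (default spacing 25 nm), including all node positions, so that every
#' sampled point lies exactly on the piecewise-linear skeleton.
#'
#' @param m a preprocessed \code{morphology}.
#' @param spacing sampling spacing in micrometers, default 0.025.
#' @param modality "full", "axon" or "dendrite".
#' @return An object of class \code{point_cloud}: a list with the N x 3
#'   \code{points} matrix and the modality tag.
#' @export
sample_points <- function(m, spacing = 0.025,
                          modality = c("full", "axon", "dendrite")) {
  modality <- match.arg(modality)
  m <- modality_subtree(m, modality)
  nd <- m$nodes
  p <- match(nd$parent, nd$id)
  pts <- list(as.matrix(nd[, c("x", "y", "z")]))
  has <- which(!is.na(p))
  for (v in has) {
    pv <- p[v]
    d <- sqrt((nd$x[v] - nd$x[pv])^2 + (nd$y[v] - nd$y[pv])^2 +
              (nd$z[v] - nd$z[pv])^2)
    k <- as.integer(ceiling(d / spacing - 1e-12))
    if (k <= 1L) next
    frac <- seq_len(k - 1L) / k
    pts[[length(pts) + 1L]] <- cbind(
      nd$x[pv] + frac * (nd$x[v] - nd$x[pv]),
      nd$y[pv] + frac * (nd$y[v] - nd$y[pv]),
      nd$z[pv] + frac * (nd$z[v] - nd$z[pv]))
  }
  points <- do.call(rbind, pts)
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, modality = modality),
            class = "point_cloud")
}

#' Fit per-axis normalization ranges over a collection of point clouds
#'
#' Density maps are comparable across cells only if all cells of a dataset
#' share the same coordinate normalization. This computes the per-axis
#' min/max over the union of the supplied clouds. Fixed ranges (e.g. from a
#' saved config) can be supplied to \code{\link{density_map}} instead.
#'
#' @param clouds a list of \code{point_cloud} objects.
#' @return An object of class \code{normalization_ranges}: a list with
#'   \code{min} and \code{max} named 3-vectors.
#' @export
fit_ranges <- function(clouds) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  stopifnot(length(clouds) >= 1L)
  all_pts <- do.call(rbind, lapply(clouds, function(cl) cl$points))
  mins <- apply(all_pts, 2, min)
  maxs <- apply(all_pts, 2, max)
  degen <- names(mins)[maxs <= mins]
  if (length(degen))
    stop("degenerate normalization axis (max = min): ",
         paste(degen, collapse = ", "))
  structure(list(min = mins, max = maxs), class = "normalization_ranges")
}

#' Serialize / restore normalization ranges
#' @param ranges a \code{normalization_ranges} object.
#' @param path JSON file path.
#' @export
write_ranges <- function(ranges, path) {
  jsonlite::write_json(lapply(unclass(ranges), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ranges
#' @export
read_ranges <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(min = unlist(raw$min), max = unlist(raw$max)),
            class = "normalization_ranges")
}

#' Smoothed neurite density map
#'
#' Normalizes a point cloud with dataset-level ranges to [0, 1] per axis,
#' projects it onto an axis or plane, bins it into 100 (1D) or 100 x 100 (2D)
#' bins spanning [-0.1, 1.1] per axis, and convolves with a unit-sum Gaussian
#' kernel (11 bins per axis, sigma = 2 bins, 'same' zero-padded output).
#' Normalized coordinates falling outside the span (possible with fixed
#' supplied ranges) are clipped into the boundary bins and counted.
#'
#' @param cloud a \code{point_cloud}.
#' @param ranges a \code{normalization_ranges}.
#' @param axis_spec one of "x", "y", "z" (1D) or "xy", "xz", "yz" (2D).
#' @param nbins bins per axis (default 100).
#' @param kernel_size,kernel_sigma smoothing kernel parameters in bins.
#' @return An object of class \code{density_map}: list with \code{values}
#'   (length-100 vector or 100 x 100 matrix), \code{axis_spec}, and
#'   \code{n_clipped}, the count of clipped points.
#' @export
density_map <- function(cloud, ranges, axis_spec,
                        nbins = 100L, kernel_size = 11L, kernel_sigma = 2) {
  axes <- strsplit(axis_spec, "")[[1]]
  if (!all(axes %in% c("x", "y", "z")) || !length(axes) %in% 1:2)
    stop("axis_spec must be one of x, y, z, xy, xz, yz")
  lo <- -0.1; hi <- 1.1
  norm <- sapply(axes, function(a)
    (cloud$points[, a] - ranges$min[[a]]) / (ranges$max[[a]] - ranges$min[[a]]))
  norm <- matrix(norm, ncol = length(axes))
  bin <- matrix(bin_index(norm, nbins, lo, hi), ncol = ncol(norm))
  clipped <- sum(bin < 1L | bin > nbins)
  bin[bin < 1L] <- 1L
  bin[bin > nbins] <- nbins
  kern <- gaussian_kernel(kernel_size, kernel_sigma)
  if (length(axes) == 1L) {
    h <- tabulate(bin[, 1L], nbins)
    values <- conv_same(h, kern)
    raw <- h
  } else {
    h <- matrix(0, nbins, nbins)
    tab <- table(factor(bin[, 1L], levels = seq_len(nbins)),
                 factor(bin[, 2L], levels = seq_len(nbins)))
    h[] <- as.numeric(tab)
    values <- conv_same_2d(h, kern)
    raw <- h
  }
  structure(list(values = values, raw = raw, axis_spec = axis_spec,
                 n_clipped = clipped, nbins = nbins),
            class = "density_map")
}

#' Flatten a density map to a feature vector
#'
#' 2D maps become 10,000 features (row-major), 1D maps 100 features.
#' @param dm a \code{density_map}.
#' @return A numeric vector.
#' @export
flatten_density_map <- function(dm) {
  v <- dm$values
  if (is.matrix(v)) as.vector(t(v)) else v
}

#' @export
print.density_map <- function(x, ...) {
  cat("Density map [", x$axis_spec, "]: ",
      if (is.matrix(x$values)) paste(dim(x$values), collapse = " x ")
      else length(x$values),
      " bins, mass ", format(sum(x$values), digits = 6), sep = "")
  if (x$n_clipped > 0) cat(" (", x$n_clipped, " clipped points)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.density_map <- function(x, ...) {
  if (is.matrix(x$values)) {
    graphics::image(seq(-0.1, 1.1, length.out = x$nbins),
                    seq(-0.1, 1.1, length.out = x$nbins),
                    x$values, xlab = substr(x$axis_spec, 1, 1),
                    ylab = substr(x$axis_spec, 2, 2),
                    col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE), ...)
  } else {
    graphics::plot(seq(-0.1, 1.1, length.out = x$nbins), x$values,
                   type = "l", xlab = x$axis_spec, ylab = "density", ...)
  }
  invisible(x)
}
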