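# Seeded generator of labelled synthetic morphologies, plus the
# hand-traceable toy trees used throughout the test suites.

#' Specification of a synthetic morphology population
#'
#' Each cell type is described by a dendritic and an axonal growth spec. The
#' defaults emulate the regime of locally projecting interneuron datasets:
#' axon-dominated cells (around 86\% of the total neurite length is axonal),
#' a compact dendritic tuft around the soma, and an axonal arbor whose
#' stratification depth (z offset of the arbor relative to the soma), lateral
#' extent and branch counts are the knobs that differ between types.
#'
#' @param types named list of type specs, each a list with fields \code{n}
#'   (cells), \code{dendrite} = list(n_stems, seg_len, seg_len_sd, depth) and
#'   \code{axon} = list(n_stems, seg_len, seg_len_sd, depth, z_offset,
#'   z_offset_sd, lateral_extent, jitter).
#' @param seed integer seed; the same seed reproduces the population
#'   byte-identically.
#' @param step growth step in micrometers between consecutive nodes.
#' @return A list of class \code{population_spec}.
#' @export
population_spec <- function(types = list(A = type_spec()), seed = 1L,
                            step = 2) {
  for (tp in types) {
    stopifnot(tp$n >= 6L, tp$dendrite$n_stems >= 1L, tp$axon$n_stems >= 1L,
              tp$dendrite$seg_len > 0, tp$axon$seg_len > 0)
  }
  structure(list(types = types, seed = as.integer(seed), step = step),
            class = "population_spec")
}

#' @rdname population_spec
#' @param n cells of this type.
#' @param dendrite,axon growth parameter lists (see above); omitted fields
#'   take the defaults.
#' @export
type_spec <- function(n = 12L, dendrite = list(), axon = list()) {
  den <- utils::modifyList(
    list(n_stems = 4L, seg_len = 30, seg_len_sd = 10, depth = 3L), dendrite)
  ax <- utils::modifyList(
    list(n_stems = 2L, seg_len = 40, seg_len_sd = 15, depth = 6L,
         z_offset = 0, z_offset_sd = 30, lateral_extent = 150, jitter = 0.3),
    axon)
  list(n = as.integer(n), dendrite = den, axon = ax)
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

#' Generate a labelled population of synthetic morphologies
#'
#' Grows each cell with a recursive bifurcating random walk: segments of
#' noisy length built from fixed-size steps whose direction is the parent
#' direction plus Gaussian jitter; the axonal arbor first descends to a
#' per-cell stratification depth drawn from the type's z-offset distribution
#' and is then confined near that depth and within the lateral extent. This
#' is deliberately a statistical stand-in, not a biophysical growth model:
#' it produces valid, controllable SWC trees with planted type differences.
#'
#' @param spec a \code{\link{population_spec}}.
#' @return list(morphologies = named list of \code{morphology},
#'   manifest = data.frame(cell, label)).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  morphs <- list(); labels <- character(0)
  cell_idx <- 0L
  for (type_name in names(spec$types)) {
    tp <- spec$types[[type_name]]
    for (i in seq_len(tp$n)) {
      cell_idx <- cell_idx + 1L
      m <- with_seed(derive_seed(spec$seed, cell_idx),
                     grow_cell(tp, spec$step))
      m$meta$label <- type_name
      m$meta$cell <- sprintf("%s_%02d", type_name, i)
      morphs[[m$meta$cell]] <- m
      labels <- c(labels, type_name)
    }
  }
  list(morphologies = morphs,
       manifest = data.frame(cell = names(morphs), label = labels))
}

grow_cell <- function(tp, step) {
  env <- new.env()
  env$rows <- list(c(1, 1, 0, 0, 0, 6, -1))
  env$counter <- 1L
  add_node <- function(type, pos, radius, parent) {
    env$counter <- env$counter + 1L
    env$rows[[env$counter]] <- c(env$counter, type, pos, radius, parent)
    env$counter
  }
  grow_branch <- function(type, pos, dir, depth, sp, parent, guide = NULL) {
    len <- max(3 * step, stats::rnorm(1, sp$seg_len, sp$seg_len_sd))
    nsteps <- max(2L, as.integer(round(len / step)))
    radius <- if (type == 2L) 0.3 else 0.6
    jit <- sp$jitter %||% 0.2
    for (s in seq_len(nsteps)) {
      dir <- dir + jit * stats::rnorm(3)
      if (!is.null(guide)) {
        # confine the axonal arbor near its stratification depth and extent
        dir[3] <- dir[3] + 0.02 * (guide$z - pos[3])
        lat <- sqrt(pos[1]^2 + pos[2]^2)
        if (lat > guide$extent)
          dir[1:2] <- dir[1:2] - 0.1 * pos[1:2] / lat
      }
      dir <- unit(dir)
      pos <- pos + dir * step
      parent <- add_node(type, pos, radius, parent)
    }
    if (depth > 1L) {
      for (b in 1:2) {
        child_dir <- unit(dir + 0.8 * rand_unit())
        grow_branch(type, pos, child_dir, depth - 1L, sp, parent, guide)
      }
    }
    invisible(NULL)
  }
  # dendrites: isotropic tuft around the soma
  for (s in seq_len(tp$dendrite$n_stems)) {
    grow_branch(3L, c(0, 0, 0), rand_unit(), tp$dendrite$depth,
                tp$dendrite, 1L)
  }
  # axon: descend to the stratification depth, then arborize there
  z_target <- stats::rnorm(1, tp$axon$z_offset, tp$axon$z_offset_sd)
  for (s in seq_len(tp$axon$n_stems)) {
    pos <- c(0, 0, 0); parent <- 1L
    goal <- c(stats::rnorm(2, 0, 10), z_target)
    d <- goal - pos
    nsteps <- max(2L, as.integer(round(vnorm(d) / step)))
    for (st in seq_len(nsteps)) {
      dirg <- unit(unit(goal - pos) + 0.1 * stats::rnorm(3))
      pos <- pos + dirg * step
      parent <- add_node(2L, pos, 0.3, parent)
    }
    grow_branch(2L, pos, unit(c(stats::rnorm(2), 0.1 * stats::rnorm(1))),
                tp$axon$depth, tp$axon, parent,
                guide = list(z = z_target, extent = tp$axon$lateral_extent))
  }
  mat <- do.call(rbind, env$rows)
  colnames(mat) <- c("id", "type", "x", "y", "z", "radius", "parent")
  morphology(as.data.frame(mat))
}

#' Hand-traceable toy morphologies
#'
#' Deterministic fixtures with known feature values, shared by the test
#' suites: \code{y_tree} (stem of length 1, daughters of lengths 2 and 1 at
#' right angles), \code{caterpillar4} (four leaves, fully unbalanced),
#' \code{balanced4} (four leaves, perfectly balanced), \code{straight}
#' (unbranched neurite of length 5), \code{trifurcation}, and
#' \code{semicircle} (a finely sampled half-circle of radius 2, tortuosity
#' pi/2).
#'
#' @return A named list of \code{morphology} objects.
#' @export
toy_fixtures <- function() {
  mk <- function(df) morphology(df)
  soma <- function() data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                                radius = 1, parent = -1L)
  node <- function(id, x, y, z, parent, type = 3L, radius = 0.5)
    data.frame(id = id, type = type, x = x, y = y, z = z, radius = radius,
               parent = parent)
  y_tree <- mk(rbind(
    soma(),
    node(2L, 0, 0, 1, 1L),                       # branch point at (0,0,1)
    node(3L, 1, 0, 1, 2L), node(4L, 2, 0, 1, 3L),  # daughter, length 2
    node(5L, 0, 1, 1, 2L)))                      # daughter, length 1
  caterpillar4 <- mk(rbind(
    soma(),
    node(2L, 0, 0, 1, 1L),
    node(3L, 1, 0, 1, 2L),
    node(4L, 0, 0, 2, 2L),
    node(5L, 1, 0, 2, 4L),
    node(6L, 0, 0, 3, 4L),
    node(7L, 1, 0, 3, 6L),
    node(8L, 0, 0, 4, 6L)))
  balanced4 <- mk(rbind(
    soma(),
    node(2L, 0, 0, 1, 1L),
    node(3L, -1, 0, 2, 2L), node(4L, 1, 0, 2, 2L),
    node(5L, -2, 0, 3, 3L), node(6L, -1, 1, 3, 3L),
    node(7L, 2, 0, 3, 4L), node(8L, 1, 1, 3, 4L)))
  straight <- mk(rbind(
    soma(),
    do.call(rbind, lapply(1:5, function(i)
      node(i + 1L, 0, 0, i, i)))))
  trifurcation <- mk(rbind(
    soma(),
    node(2L, 0, 0, 1, 1L),
    node(3L, 1, 0, 2, 2L), node(4L, -1, 0, 2, 2L), node(5L, 0, 1, 2, 2L)))
  theta <- seq(0, pi, length.out = 1001L)[-1L]
  r <- 2
  semicircle <- mk(rbind(
    soma(),
    data.frame(id = seq_along(theta) + 1L, type = 3L,
               x = r - r * cos(theta), y = r * sin(theta), z = 0,
               radius = 0.5,
               parent = seq_along(theta))))
  list(y_tree = y_tree, caterpillar4 = caterpillar4, balanced4 = balanced4,
       straight = straight, trifurcation = trifurcation,
       semicircle = semicircle)
}
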