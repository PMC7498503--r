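# Morphometric statistics (24 single-valued summaries), 1D and 2D
# morphometric distributions, Sholl profiles and 3-star motif vectors.

warn_zero <- function(what) {
  warning(what, " undefined for this topology; recorded as 0", call. = FALSE)
  0
}

pctl <- function(x, p) as.numeric(stats::quantile(x, p, type = 7, na.rm = TRUE))

#' Tree asymmetry (weighted sum of PSADs)
#'
#' For each branch point p with out-degree m whose subtree has n leaves split
#' as r_1..r_m between its children, the proportional sum of absolute
#' deviations is
#' \deqn{PSAD(p) = m / (2 (m-1)(n-m)) \sum_i |r_i - n/m|,}
#' a balance score in [0, 1]. The tree asymmetry is the sum of PSAD(p) over
#' all branch points whose subtree has more than 3 leaves (weight 1, else 0).
#'
#' @param m a \code{morphology}.
#' @return A non-negative scalar; 0 for trees without branch points.
#' @export
tree_asymmetry <- function(m) {
  ts <- tree_structure(m)
  if (!length(ts$branch_points) && ts$n_children[ts$root] < 2L) return(0)
  n <- nrow(m$nodes)
  leaves <- integer(n)
  leaves[ts$tips] <- 1L
  for (v in rev(seq_len(n))) {
    p <- ts$parent_row[v]
    if (!is.na(p)) leaves[p] <- leaves[p] + leaves[v]
  }
  total <- 0
  bps <- which(ts$n_children >= 2L)            # includes a multi-stem root
  for (b in bps) {
    r <- leaves[ts$children[[b]]]
    mm <- length(r); nn <- sum(r)
    if (nn <= 3L) next
    if (nn == mm) next                         # all children are tips: balanced
    psad <- mm / (2 * (mm - 1) * (nn - mm)) * sum(abs(r - nn / mm))
    total <- total + psad
  }
  total
}

#' The 24 morphometric statistics
#'
#' Single-valued summaries of one (modality) morphology: branch point / tip /
#' stem counts, z/x/y extents, average neurite radius, total path length,
#' truncated-cone surface area and volume, maximal neurite length, maximum
#' centrifugal branch order, maximal Euclidean segment length, median
#' intermediate and terminal segment path lengths, median and 99.5th
#' percentile path angle, median and 99.5th percentile log-tortuosity,
#' minimal/average/maximal branch angle, maximal node degree, and tree
#' asymmetry. The soma is excluded from thickness, surface and volume.
#' Statistics undefined for a degenerate topology are recorded as 0 with a
#' warning so feature matrices stay finite.
#'
#' @param g a \code{geometry_tables} object.
#' @return A named numeric vector of length 24 of class
#'   \code{morphometric_statistics}.
#' @export
compute_statistics <- function(g) {
  nd <- g$nodes
  seg <- g$segments
  neur <- nd[nd$type != 1L, , drop = FALSE]
  ed <- g$edges

  surface <- sum(pi * (ed$r_parent + ed$r_child) *
                 sqrt((ed$r_child - ed$r_parent)^2 + ed$length^2))
  volume <- sum(pi / 3 * ed$length *
                (ed$r_parent^2 + ed$r_parent * ed$r_child + ed$r_child^2))

  pa <- nd$path_angle[!is.na(nd$path_angle)]
  tort <- log(seg$tortuosity[!is.na(seg$tortuosity) & seg$tortuosity > 0])
  ba <- g$branch_angles$angle[!is.na(g$branch_angles$angle)]
  inter <- seg$length[seg$kind == "intermediate"]
  term <- seg$length[seg$kind == "terminal"]

  out <- c(
    n_branch_points = nrow(g$branch_points),
    n_tips = sum(nd$is_tip),
    height = diff(range(nd$z)),
    width = diff(range(nd$x)),
    depth = diff(range(nd$y)),
    n_stems = g$n_stems,
    avg_thickness = if (nrow(neur)) mean(neur$radius) else warn_zero("average thickness"),
    total_length = sum(ed$length),
    surface = surface,
    volume = volume,
    max_neurite_length = if (any(nd$is_tip)) max(nd$path_dist[nd$is_tip]) else 0,
    max_branch_order = max(nd$branch_order),
    max_segment = if (nrow(seg)) max(seg$eucl) else 0,
    median_intermediate_segment = if (length(inter)) stats::median(inter)
      else warn_zero("median intermediate segment"),
    median_terminal_segment = if (length(term)) stats::median(term)
      else warn_zero("median terminal segment"),
    median_path_angle = if (length(pa)) stats::median(pa)
      else warn_zero("median path angle"),
    max_path_angle = if (length(pa)) pctl(pa, 0.995)
      else warn_zero("maximal path angle"),
    median_log_tortuosity = if (length(tort)) stats::median(tort)
      else warn_zero("median log-tortuosity"),
    max_log_tortuosity = if (length(tort)) pctl(tort, 0.995)
      else warn_zero("maximal log-tortuosity"),
    min_branch_angle = if (length(ba)) min(ba) else warn_zero("minimal branch angle"),
    avg_branch_angle = if (length(ba)) mean(ba) else warn_zero("average branch angle"),
    max_branch_angle = if (length(ba)) max(ba) else warn_zero("maximal branch angle"),
    max_degree = if (nrow(g$branch_points)) max(g$branch_points$out_degree) + 1L
      else warn_zero("maximal degree"),
    tree_asymmetry = tree_asymmetry(g$morphology)
  )
  class(out) <- c("morphometric_statistics", class(out))
  out
}

#' @export
print.morphometric_statistics <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Dataset-level bin maxima for morphometric distributions
#'
#' Several distribution bins are scaled by dataset maxima (longest segment,
#' thickest neurite, longest neurite, highest branch order). Computed once
#' per dataset and modality over a list of geometry tables; serializable to
#' JSON alongside the density-map normalization ranges.
#'
#' @param geoms list of \code{geometry_tables}.
#' @return A list with \code{max_segment_length}, \code{max_radius},
#'   \code{max_neurite_length}, \code{max_branch_order}.
#' @export
dataset_edges <- function(geoms) {
  if (inherits(geoms, "geometry_tables")) geoms <- list(geoms)
  list(
    max_segment_length = max(vapply(geoms, function(g)
      if (nrow(g$segments)) max(g$segments$eucl) else 0, 0)),
    max_radius = max(vapply(geoms, function(g) {
      r <- g$nodes$radius[g$nodes$type != 1L]
      if (length(r)) max(r) else 0
    }, 0)),
    max_neurite_length = max(vapply(geoms, function(g)
      max(g$nodes$path_dist), 0)),
    max_branch_order = max(vapply(geoms, function(g)
      max(g$nodes$branch_order), 0))
  )
}

hist2_counts <- function(x, y, nbx, lox, hix, nby, loy, hiy) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  out <- matrix(0, nbx, nby)
  if (!length(x)) return(out)
  clampbin <- function(v, nb, lo, hi) {
    i <- bin_index(v, nb, lo, hi)
    i[i < 1L] <- 1L; i[i > nb] <- nb
    i
  }
  ix <- clampbin(x, nbx, lox, hix)
  iy <- clampbin(y, nby, loy, hiy)
  for (k in seq_along(ix)) out[ix[k], iy[k]] <- out[ix[k], iy[k]] + 1
  out
}

dist_1d_names <- c("branch_angles", "branch_orders", "path_angles",
                   "root_angles", "euler_alpha", "euler_beta", "euler_gamma",
                   "segment_lengths", "thickness", "path_dist", "eucl_dist",
                   "sholl_xy", "sholl_xz", "sholl_yz",
                   "star_motif", "avg_star_motif", "avg_max_distance")

dist_2d_names <- c("branch_angle_x_branch_order", "branch_angle_x_path_dist",
                   "path_angle_x_branch_order", "path_angle_x_path_dist",
                   "thickness_x_branch_order", "thickness_x_path_dist")

#' One-dimensional morphometric distributions
#'
#' The 17 binned distributions: branch angles, branch orders, path angles,
#' root angles, the three Euler root angles (each 20 bins over [0, 180] for
#' angles), Euclidean segment lengths (20 bins to the dataset maximum),
#' node radii (30 bins to the dataset maximum, soma excluded), path and
#' Euclidean distances of branch points and tips to the soma (20 bins to the
#' dataset maximal neurite length), Sholl intersection profiles in three
#' projection planes (36 circles), and the soma-centered / random-center
#' averaged 3-star motif and maximal-distance decile vectors. Histograms
#' store raw counts.
#'
#' @param g a \code{geometry_tables} object.
#' @param name one of the 17 distribution names (see
#'   \code{morphrep_distributions()}).
#' @param edges dataset bin maxima from \code{\link{dataset_edges}}.
#' @param nbins optional override of the bin count (used e.g. to check 2D
#'   marginal consistency); defaults to the documented binning.
#' @param n_repeats,seed for the random-center averaged vectors.
#' @return An object of class \code{morph_distribution} with \code{values}.
#' @export
distribution_1d <- function(g, name, edges = dataset_edges(g),
                            nbins = NULL, n_repeats = 100L, seed = 1L) {
  nd <- g$nodes
  seg <- g$segments
  bt <- nd[nd$is_tip | nd$is_branch_point, , drop = FALSE]
  values <- switch(
    name,
    branch_angles = hist_counts(g$branch_angles$angle, nbins %||% 20L, 0, 180),
    branch_orders = {
      K <- edges$max_branch_order
      tabulate(factor(g$branch_points$branch_order, levels = 0:K), K + 1L)
    },
    path_angles = hist_counts(nd$path_angle, nbins %||% 20L, 0, 180),
    root_angles = hist_counts(seg$root_angle, nbins %||% 20L, 0, 180),
    euler_alpha = hist_counts(seg$euler_alpha, nbins %||% 20L, 0, 180),
    euler_beta = hist_counts(seg$euler_beta, nbins %||% 20L, 0, 180),
    euler_gamma = hist_counts(seg$euler_gamma, nbins %||% 20L, 0, 180),
    segment_lengths = hist_counts(seg$eucl, nbins %||% 20L, 0,
                                  edges$max_segment_length),
    thickness = hist_counts(nd$radius[nd$type != 1L], nbins %||% 30L, 0,
                            edges$max_radius),
    path_dist = hist_counts(bt$path_dist, nbins %||% 20L, 0,
                            edges$max_neurite_length),
    eucl_dist = hist_counts(bt$eucl_dist, nbins %||% 20L, 0,
                            edges$max_neurite_length),
    sholl_xy = sholl_profile(g, "xy"),
    sholl_xz = sholl_profile(g, "xz"),
    sholl_yz = sholl_profile(g, "yz"),
    star_motif = star_motifs(g$morphology, centers = "soma"),
    avg_star_motif = star_motifs(g$morphology, centers = "random",
                                 n_repeats = n_repeats, seed = seed),
    avg_max_distance = average_maximal_distance(g$morphology,
                                                n_repeats = n_repeats,
                                                seed = seed),
    stop("unknown 1D distribution: ", name)
  )
  structure(list(name = name, values = as.numeric(values)),
            class = "morph_distribution")
}

#' Two-dimensional morphometric distributions
#'
#' The six 20 x 20 joint histograms (branch angle / path angle / thickness
#' against branch order or path distance to soma), flattened row-major to
#' 400 features. Binning matches the 1D distributions; the branch-order axis
#' spans [0, dataset maximal order] and the path-distance axis
#' [0, dataset maximal neurite length].
#'
#' @inheritParams distribution_1d
#' @param name one of the six 2D distribution names.
#' @return A \code{morph_distribution} whose \code{values} has length 400;
#'   the 20 x 20 matrix is kept in \code{matrix}.
#' @export
distribution_2d <- function(g, name, edges = dataset_edges(g)) {
  nd <- g$nodes
  ba <- g$branch_angles
  K <- edges$max_branch_order
  L <- edges$max_neurite_length
  pa_nodes <- nd[!is.na(nd$path_angle), , drop = FALSE]
  th_nodes <- nd[nd$type != 1L, , drop = FALSE]
  mat <- switch(
    name,
    branch_angle_x_branch_order =
      hist2_counts(ba$angle, ba$branch_order, 20L, 0, 180, 20L, 0, K),
    branch_angle_x_path_dist =
      hist2_counts(ba$angle, ba$path_dist, 20L, 0, 180, 20L, 0, L),
    path_angle_x_branch_order =
      hist2_counts(pa_nodes$path_angle, pa_nodes$branch_order,
                   20L, 0, 180, 20L, 0, K),
    path_angle_x_path_dist =
      hist2_counts(pa_nodes$path_angle, pa_nodes$path_dist,
                   20L, 0, 180, 20L, 0, L),
    thickness_x_branch_order =
      hist2_counts(th_nodes$radius, th_nodes$branch_order,
                   20L, 0, edges$max_radius, 20L, 0, K),
    thickness_x_path_dist =
      hist2_counts(th_nodes$radius, th_nodes$path_dist,
                   20L, 0, edges$max_radius, 20L, 0, L),
    stop("unknown 2D distribution: ", name)
  )
  structure(list(name = name, values = as.numeric(t(mat)), matrix = mat),
            class = "morph_distribution")
}

#' Names of the implemented morphometric distributions
#' @return list with components \code{one_d} and \code{two_d}.
#' @export
morphrep_distributions <- function() {
  list(one_d = dist_1d_names, two_d = dist_2d_names)
}

#' Sholl intersection profile
#'
#' Counts the intersections of the 2D-projected skeleton with 36 concentric
#' circles around the projected soma, with radii equally spaced from the soma
#' to the maximal radial distance of any node.
#'
#' @param g a \code{geometry_tables} object.
#' @param plane "xy", "xz" or "yz".
#' @return An integer vector of length 36.
#' @export
sholl_profile <- function(g, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  nd <- g$nodes
  px <- nd[[ax[1]]] - g$soma[[ax[1]]]
  py <- nd[[ax[2]]] - g$soma[[ax[2]]]
  r <- sqrt(px^2 + py^2)
  R <- max(r)
  counts <- numeric(36L)
  if (R <= 0) return(counts)
  step <- R / 36
  ed <- g$edges
  id_row <- match(nd$id, nd$id)  # identity; edges store row indices already
  lo <- pmin(r[ed$child], r[ed$parent])
  hi <- pmax(r[ed$child], r[ed$parent])
  kmin <- floor(lo / step + 1e-9) + 1L
  kmax <- floor(hi / step + 1e-9)
  kmax[kmax > 36L] <- 36L
  for (e in seq_along(kmin)) {
    if (kmin[e] <= kmax[e])
      counts[kmin[e]:kmax[e]] <- counts[kmin[e]:kmax[e]] + 1
  }
  counts
}

# undirected adjacency + edge lengths for path distances from any node
tree_adjacency <- function(m) {
  ts <- tree_structure(m)
  el <- edge_lengths(m, ts)
  n <- nrow(m$nodes)
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (v in seq_len(n)) {
    p <- ts$parent_row[v]
    if (is.na(p)) next
    adj[[v]] <- c(adj[[v]], p); wts[[v]] <- c(wts[[v]], el[v])
    adj[[p]] <- c(adj[[p]], v); wts[[p]] <- c(wts[[p]], el[v])
  }
  list(adj = adj, wts = wts, ts = ts)
}

path_dist_from <- function(ad, center) {
  n <- length(ad$adj)
  d <- rep(NA_real_, n)
  d[center] <- 0
  queue <- center
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- ad$adj[[v]]
    for (i in seq_along(nb)) {
      w <- nb[i]
      if (is.na(d[w])) {
        d[w] <- d[v] + ad$wts[[v]][i]
        queue <- c(queue, w)
      }
    }
  }
  d
}

star_motif_count <- function(ad, node_set) {
  inset <- logical(length(ad$adj))
  inset[node_set] <- TRUE
  total <- 0L
  for (v in node_set) {
    degv <- sum(inset[ad$adj[[v]]])
    if (degv >= 3L) total <- total + degv - 2L
  }
  total
}

#' 3-star motif decile vectors
#'
#' Element i counts the 3-star motifs (a node of degree d >= 3 contributes
#' d - 2 motifs, so a trifurcation counts twice) in the sub-graph induced by
#' the i*10\% of nodes closest (by path distance) to the center. With
#' \code{centers = "random"} the vector is averaged over \code{n_repeats}
#' random center nodes drawn with a fixed seed.
#'
#' @param m a \code{morphology}.
#' @param centers "soma" or "random".
#' @param n_repeats number of random centers for the averaged variant.
#' @param seed RNG seed for the random centers.
#' @return A numeric vector of length 10 (non-decreasing for fixed center).
#' @export
star_motifs <- function(m, centers = c("soma", "random"), n_repeats = 100L,
                        seed = 1L) {
  centers <- match.arg(centers)
  ad <- tree_adjacency(m)
  n <- length(ad$adj)
  one_center <- function(center) {
    d <- path_dist_from(ad, center)
    ord <- order(d, seq_len(n))
    vapply(1:10, function(i) {
      k <- ceiling(i / 10 * n)
      star_motif_count(ad, ord[seq_len(k)])
    }, 0L)
  }
  if (centers == "soma") return(as.numeric(one_center(soma_row(m))))
  with_seed(seed, {
    picks <- sample.int(n, n_repeats, replace = TRUE)
    rowMeans(vapply(picks, one_center, integer(10L)))
  })
}

#' Averaged maximal-distance decile vector
#'
#' Companion of the averaged 3-star motif vector: for the same nested decile
#' sub-graphs around random center nodes, the maximal Euclidean distance from
#' the center to any sub-graph node, averaged over \code{n_repeats} draws.
#'
#' @inheritParams star_motifs
#' @return A numeric vector of length 10.
#' @export
average_maximal_distance <- function(m, n_repeats = 100L, seed = 1L) {
  ad <- tree_adjacency(m)
  n <- length(ad$adj)
  xyz <- as.matrix(m$nodes[, c("x", "y", "z")])
  one_center <- function(center) {
    d <- path_dist_from(ad, center)
    ord <- order(d, seq_len(n))
    ec <- sqrt(colSums((t(xyz) - xyz[center, ])^2))
    vapply(1:10, function(i) {
      k <- ceiling(i / 10 * n)
      max(ec[ord[seq_len(k)]])
    }, 0)
  }
  with_seed(seed, {
    picks <- sample.int(n, n_repeats, replace = TRUE)
    rowMeans(vapply(picks, one_center, numeric(10L)))
  })
}
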