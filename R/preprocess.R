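# Preprocessing chain: soma consolidation, branch-type harmonization,
# resampling, depth-axis smoothing, centering.

# Maximal unbranched runs: for every topology node (root, branch point) and
# each of its children, the path down to the next branch point or tip.
# Returns a list of integer row vectors, start and end node inclusive.
segment_paths <- function(m, ts = tree_structure(m)) {
  topo <- ts$n_children >= 2L
  topo[ts$root] <- TRUE
  out <- list()
  for (t in which(topo)) {
    for (c0 in ts$children[[t]]) {
      path <- c(t, c0)
      v <- c0
      while (ts$n_children[v] == 1L) {
        v <- ts$children[[v]][1L]
        path <- c(path, v)
      }
      out[[length(out) + 1L]] <- path
    }
  }
  out
}

#' Consolidate all somatic nodes into a single root node
#'
#' Reconstructions may contain several nodes labelled as soma (or, for
#' datasets missing explicit soma labels, thick nodes that should be somatic).
#' All somatic nodes are replaced by one root node positioned at the centroid
#' of the somatic node cluster, and the tree is re-rooted there; children of
#' removed somatic nodes are re-parented to the new soma.
#'
#' @param m a \code{morphology}.
#' @param radius_threshold if given, every node with radius strictly larger
#'   than this value (in micrometers) is relabelled as somatic before
#'   grouping. Used for datasets without explicit soma labels.
#' @return A \code{morphology} with exactly one soma node as root.
#' @export
consolidate_soma <- function(m, radius_threshold = NULL) {
  nd <- m$nodes
  if (!is.null(radius_threshold))
    nd$type[nd$radius > radius_threshold] <- 1L
  soma <- which(nd$type == 1L)
  if (!length(soma)) stop("no soma identifiable")
  root <- which(nd$parent == -1L)
  if (length(soma) == 1L && soma == root && is.null(radius_threshold))
    return(m)
  if (length(soma) == 1L && soma == root) {
    m$nodes <- nd
    return(m)
  }
  pos <- unique(nd[soma, c("x", "y", "z")])
  # centroid of the somatic cluster (vertex centroid of its convex hull;
  # duplicated positions are collapsed first)
  centroid <- colMeans(pos)
  soma_radius <- mean(nd$radius[soma])
  new_id <- max(nd$id) + 1L

  # contract the somatic nodes to a supernode and re-root the tree there
  keep <- setdiff(seq_len(nrow(nd)), soma)
  parent_row <- match(nd$parent, nd$id)
  adj <- vector("list", nrow(nd) + 1L)       # last entry = supernode
  sn <- nrow(nd) + 1L
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (v in seq_len(nrow(nd))) {
    p <- parent_row[v]
    if (is.na(p)) next
    a <- if (v %in% soma) sn else v
    b <- if (p %in% soma) sn else p
    if (a != b) add_edge(a, b)
  }
  new_parent <- rep(NA_integer_, nrow(nd))
  visited <- rep(FALSE, nrow(nd) + 1L)
  visited[sn] <- TRUE
  queue <- adj[[sn]]
  for (v in queue) if (!visited[v]) { visited[v] <- TRUE; new_parent[v] <- 0L }
  queue <- unique(queue[queue != sn])
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        new_parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (!all(visited[keep])) stop("somatic consolidation disconnected the tree")
  out <- nd[keep, , drop = FALSE]
  out$parent <- ifelse(new_parent[keep] == 0L, new_id, nd$id[new_parent[keep]])
  soma_node <- data.frame(id = new_id, type = 1L, x = centroid[["x"]],
                          y = centroid[["y"]], z = centroid[["z"]],
                          radius = soma_radius, parent = -1L)
  morphology(rbind(soma_node, out), m$meta)
}

#' Harmonize compartment types within each branch
#'
#' Within one unbranched neurite run the SWC type labels can be inconsistent
#' between consecutive nodes. Each branch is relabelled by the majority vote
#' over its sub-segment types; exact axon/dendrite ties resolve to axon.
#' The soma node is exempt.
#'
#' @param m a single-soma \code{morphology}.
#' @return A \code{morphology} with branch-consistent types.
#' @export
harmonize_branch_types <- function(m) {
  ts <- tree_structure(m)
  nd <- m$nodes
  for (path in segment_paths(m, ts)) {
    rows <- path[-1L]                         # sub-segment type = child type
    types <- nd$type[rows]
    types <- types[types != 1L]
    if (!length(types)) next
    n_axon <- sum(types == 2L)
    maj <- if (n_axon >= length(types) / 2) 2L else 3L
    set <- rows[nd$type[rows] != 1L]
    nd$type[set] <- maj
  }
  m$nodes <- nd
  m
}

#' Resample a morphology to (at most) a given inter-node spacing
#'
#' Every sub-segment (straight line between consecutive nodes) of length d is
#' linearly subdivided into \code{ceiling(d / spacing)} equal pieces, so that
#' consecutive nodes along any neurite are at most \code{spacing} apart.
#' Branch points, tips and the soma are retained exactly and the total path
#' length is preserved. The operation is idempotent.
#'
#' @param m a \code{morphology}.
#' @param spacing target spacing in micrometers (> 0).
#' @return A resampled \code{morphology} with consecutively renumbered ids.
#' @export
resample <- function(m, spacing = 1) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  nd <- m$nodes
  parent_row <- match(nd$parent, nd$id)
  n <- nrow(nd)
  new_row <- integer(n)                       # new id of each original node
  id_counter <- 0L
  rows <- vector("list", n)
  for (v in seq_len(n)) {
    p <- parent_row[v]
    if (is.na(p)) {
      id_counter <- id_counter + 1L
      new_row[v] <- id_counter
      rows[[v]] <- data.frame(id = id_counter, type = nd$type[v], x = nd$x[v],
                              y = nd$y[v], z = nd$z[v], radius = nd$radius[v],
                              parent = -1L)
      next
    }
    d <- sqrt((nd$x[v] - nd$x[p])^2 + (nd$y[v] - nd$y[p])^2 +
              (nd$z[v] - nd$z[p])^2)
    k <- max(1L, as.integer(ceiling(d / spacing - 1e-12)))
    frac <- seq_len(k) / k
    ids <- id_counter + seq_len(k)
    id_counter <- id_counter + k
    new_row[v] <- ids[k]
    rows[[v]] <- data.frame(
      id = ids, type = nd$type[v],
      x = nd$x[p] + frac * (nd$x[v] - nd$x[p]),
      y = nd$y[p] + frac * (nd$y[v] - nd$y[p]),
      z = nd$z[p] + frac * (nd$z[v] - nd$z[p]),
      radius = nd$radius[p] + frac * (nd$radius[v] - nd$radius[p]),
      parent = c(new_row[p], ids[-k] + 0L)[seq_len(k)])
  }
  out <- do.call(rbind, rows)
  renumber_nodes(morphology(out, m$meta))
}

# Renumber ids to the (topologically sorted) row order; keeps repeated
# resampling byte-stable.
renumber_nodes <- function(m) {
  nd <- m$nodes
  new_id <- seq_len(nrow(nd))
  prow <- match(nd$parent, nd$id)
  nd$id <- new_id
  nd$parent <- ifelse(is.na(prow), -1L, new_id[prow])
  m$nodes <- nd
  m
}

#' Smooth the slice-depth (y) coordinate along unbranched runs
#'
#' Biocytin reconstructions can show sudden jumps in the coordinate along the
#' viewing direction of the microscope. After resampling to ~1 um spacing a
#' Savitzky-Golay filter (window in micrometers ~ window in samples) is
#' applied to the y coordinate of every unbranched run; runs shorter than the
#' window are left unfiltered, and run endpoints (soma, branch points, tips)
#' are kept fixed so the tree stays consistent.
#'
#' @param m a resampled \code{morphology}.
#' @param window filter window length in samples (odd), default 21.
#' @param order polynomial order, default 3.
#' @return A \code{morphology} with smoothed y coordinates.
#' @export
smooth_depth_axis <- function(m, window = 21L, order = 3L) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  nd <- m$nodes
  for (path in segment_paths(m)) {
    if (length(path) < window) next
    sm <- signal::sgolayfilt(nd$y[path], p = order, n = window)
    interior <- path[-c(1L, length(path))]
    nd$y[interior] <- sm[-c(1L, length(sm))]
  }
  m$nodes <- nd
  m
}

#' Center a morphology
#'
#' Cortical interneurons are soma-centered in all three axes. Retinal bipolar
#' cells are soma-centered in x and y while z is shifted by a dataset-supplied
#' offset so that z = 0 corresponds to the onset of the inner plexiform layer.
#'
#' @param m a single-soma \code{morphology}.
#' @param mode "soma" or "soma_xy_with_z_offset".
#' @param z_offset shift added to all z coordinates in the bipolar mode.
#' @return A centered \code{morphology}.
#' @export
center_morphology <- function(m, mode = c("soma", "soma_xy_with_z_offset"),
                              z_offset = 0) {
  mode <- match.arg(mode)
  s <- soma_row(m)
  nd <- m$nodes
  nd$x <- nd$x - nd$x[s]
  nd$y <- nd$y - nd$y[s]
  if (mode == "soma") nd$z <- nd$z - nd$z[s] else nd$z <- nd$z + z_offset
  m$nodes <- nd
  m
}

#' Full preprocessing chain
#'
#' Applies soma consolidation, branch-type harmonization and centering;
#' in cortical mode additionally resamples to ~1 um node spacing and smooths
#' the slice-depth (y) axis. In bipolar mode a 1 um radius threshold is used
#' to identify somatic nodes and z is offset to the IPL onset.
#'
#' @param m a raw \code{morphology}.
#' @param mode "cortical" or "bipolar".
#' @param spacing resampling spacing (cortical mode), micrometers.
#' @param savgol_window,savgol_order Savitzky-Golay parameters (cortical mode).
#' @param radius_threshold somatic radius threshold (bipolar mode).
#' @param z_offset IPL offset (bipolar mode), micrometers.
#' @return A preprocessed \code{morphology}.
#' @export
preprocess_morphology <- function(m, mode = c("cortical", "bipolar"),
                                  spacing = 1, savgol_window = 21L,
                                  savgol_order = 3L, radius_threshold = 1,
                                  z_offset = 0) {
  mode <- match.arg(mode)
  if (mode == "cortical") {
    m <- consolidate_soma(m)
    m <- harmonize_branch_types(m)
    m <- resample(m, spacing)
    m <- smooth_depth_axis(m, savgol_window, savgol_order)
    m <- center_morphology(m, "soma")
  } else {
    m <- consolidate_soma(m, radius_threshold = radius_threshold)
    m <- harmonize_branch_types(m)
    m <- center_morphology(m, "soma_xy_with_z_offset", z_offset = z_offset)
  }
  m
}
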