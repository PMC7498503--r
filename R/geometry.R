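# Per-node / per-branch-point / per-segment geometry consumed by all
# feature modules.

#' Induced subtree of one compartment kind
#'
#' Selects the nodes belonging to a modality (full neuron, axon only or
#' dendrite only). The soma is always included as root; kept nodes whose
#' parents were dropped are re-parented to their nearest kept ancestor.
#'
#' @param m a preprocessed \code{morphology}.
#' @param modality "full", "axon" or "dendrite".
#' @return A \code{morphology}.
#' @export
modality_subtree <- function(m, modality = c("full", "axon", "dendrite")) {
  modality <- match.arg(modality)
  if (modality == "full") return(m)
  want <- if (modality == "axon") 2L else 3L
  nd <- m$nodes
  keep <- nd$type == want | nd$type == 1L
  if (sum(nd$type[keep] == want) == 0L)
    stop("empty modality: no ", modality, " nodes")
  parent_row <- match(nd$parent, nd$id)
  # nearest kept ancestor, computable in one topological pass
  anc <- integer(nrow(nd))
  for (v in seq_len(nrow(nd))) {
    p <- parent_row[v]
    if (is.na(p)) anc[v] <- v
    else anc[v] <- if (keep[p]) p else anc[p]
  }
  out <- nd[keep, , drop = FALSE]
  sel <- which(keep)
  newpar <- integer(length(sel))
  for (i in seq_along(sel)) {
    v <- sel[i]
    p <- parent_row[v]
    newpar[i] <- if (is.na(p)) -1L else nd$id[anc[v]]
  }
  out$parent <- newpar
  morphology(out, m$meta)
}

#' Geometry tables of a morphology
#'
#' Computes every per-node, per-branch-point and per-segment quantity the
#' feature representations build on: centrifugal branch order (soma = 0),
#' path and Euclidean distance to the soma, path angles (angle between
#' consecutive direction vectors, so a straight continuation scores 0
#' degrees), branch angles at branch points, segment path/Euclidean lengths,
#' tortuosity, root angles and Euler root angles. All angles are in degrees
#' within [0, 180].
#'
#' @param m a preprocessed \code{morphology}.
#' @param modality "full", "axon" or "dendrite" (subtree of that kind).
#' @return An object of class \code{geometry_tables}: a list with components
#'   \code{nodes}, \code{edges}, \code{branch_points}, \code{branch_angles},
#'   \code{segments}, and \code{soma} (root coordinates).
#' @export
geometry_tables <- function(m, modality = c("full", "axon", "dendrite")) {
  modality <- match.arg(modality)
  m <- modality_subtree(m, modality)
  nd <- m$nodes
  ts <- tree_structure(m)
  n <- nrow(nd)
  p <- ts$parent_row
  elen <- edge_lengths(m, ts)

  is_bp <- ts$n_children >= 2L
  is_bp[ts$root] <- FALSE                      # stems keep order 0

  order <- integer(n); pathd <- numeric(n)
  for (v in seq_len(n)) {
    if (is.na(p[v])) next
    order[v] <- order[p[v]] + as.integer(is_bp[p[v]])
    pathd[v] <- pathd[p[v]] + elen[v]
  }
  s <- ts$root
  eucl <- sqrt((nd$x - nd$x[s])^2 + (nd$y - nd$y[s])^2 + (nd$z - nd$z[s])^2)

  # path angle at each node with exactly one child and a parent
  path_angle <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (is.na(p[v]) || ts$n_children[v] != 1L) next
    w <- ts$children[[v]][1L]
    a <- c(nd$x[v] - nd$x[p[v]], nd$y[v] - nd$y[p[v]], nd$z[v] - nd$z[p[v]])
    b <- c(nd$x[w] - nd$x[v], nd$y[w] - nd$y[v], nd$z[w] - nd$z[v])
    path_angle[v] <- vec_angle(a, b)
  }

  nodes <- data.frame(id = nd$id, type = nd$type, x = nd$x, y = nd$y,
                      z = nd$z, radius = nd$radius,
                      branch_order = order, path_dist = pathd,
                      eucl_dist = eucl, path_angle = path_angle,
                      is_tip = ts$n_children == 0L, is_branch_point = is_bp)

  edges <- data.frame(child = which(!is.na(p)))
  edges$parent <- p[edges$child]
  edges$length <- elen[edges$child]
  edges$r_child <- nd$radius[edges$child]
  edges$r_parent <- ifelse(edges$parent == s, nd$radius[edges$child],
                           nd$radius[edges$parent])  # soma radius excluded

  bp_rows <- which(is_bp)
  branch_points <- data.frame(id = nd$id[bp_rows],
                              out_degree = ts$n_children[bp_rows],
                              branch_order = order[bp_rows],
                              path_dist = pathd[bp_rows])
  ba <- list()
  for (b in bp_rows) {
    kids <- ts$children[[b]]
    dirs <- lapply(kids, function(k)
      c(nd$x[k] - nd$x[b], nd$y[k] - nd$y[b], nd$z[k] - nd$z[b]))
    for (i in seq_along(kids)) for (j in seq_along(kids)) {
      if (i >= j) next
      ba[[length(ba) + 1L]] <- data.frame(
        bp_id = nd$id[b], angle = vec_angle(dirs[[i]], dirs[[j]]),
        branch_order = order[b], path_dist = pathd[b])
    }
  }
  branch_angles <- if (length(ba)) do.call(rbind, ba) else
    data.frame(bp_id = integer(), angle = numeric(),
               branch_order = integer(), path_dist = numeric())

  segs <- segment_paths(m, ts)
  seg_tab <- lapply(segs, function(path) {
    i0 <- path[1L]; i1 <- path[length(path)]
    plen <- sum(elen[path[-1L]])
    chord <- c(nd$x[i1] - nd$x[i0], nd$y[i1] - nd$y[i0], nd$z[i1] - nd$z[i0])
    ec <- vnorm(chord)
    radial <- c(nd$x[i1] - nd$x[s], nd$y[i1] - nd$y[s], nd$z[i1] - nd$z[s])
    euler <- euler_alignment_angles(radial, chord)
    data.frame(start_id = nd$id[i0], end_id = nd$id[i1],
               length = plen, eucl = ec,
               tortuosity = if (ec > 0) plen / ec else NA_real_,
               kind = if (ts$n_children[i1] == 0L) "terminal" else "intermediate",
               branch_order = order[path[2L]],
               start_path_dist = pathd[i0],
               root_angle = vec_angle(chord, radial),
               euler_alpha = euler[1L], euler_beta = euler[2L],
               euler_gamma = euler[3L])
  })
  segments <- do.call(rbind, seg_tab)

  structure(list(nodes = nodes, edges = edges, branch_points = branch_points,
                 branch_angles = branch_angles, segments = segments,
                 soma = c(x = nd$x[s], y = nd$y[s], z = nd$z[s]),
                 n_stems = length(ts$children[[s]]),
                 modality = modality, morphology = m),
            class = "geometry_tables")
}

# Euler angles (extrinsic rotations about the fixed x, y, z axes, i.e.
# R = Rz(gamma) Ry(beta) Rx(alpha)) of the minimal rotation aligning the
# soma-to-segment-end direction with the segment chord. Reported as absolute
# values in [0, 180] degrees.
euler_alignment_angles <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu == 0 || nv == 0) return(c(NA_real_, NA_real_, NA_real_))
  u <- u / nu; v <- v / nv
  ct <- min(1, max(-1, sum(u * v)))
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  na <- vnorm(axis)
  if (na < 1e-12) {
    if (ct > 0) return(c(0, 0, 0))
    # antiparallel: rotate 180 degrees about any axis perpendicular to u
    perp <- if (abs(u[1]) < 0.9) unit(c(0, -u[3], u[2])) else unit(c(-u[2], u[1], 0))
    axis <- perp; theta <- pi
  } else {
    axis <- axis / na
    theta <- acos(ct)
  }
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  beta <- asin(min(1, max(-1, -R[3, 1])))
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  abs(c(deg(alpha), deg(beta), deg(gamma)))
}

#' @export
print.geometry_tables <- function(x, ...) {
  cat("Geometry tables (", x$modality, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$branch_points), " branch points, ", nrow(x$segments),
      " segments\n", sep = "")
  invisible(x)
}
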