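#' Neuron morphologies from SWC reconstructions
#'
#' A morphology is a rooted tree of 3D nodes, each carrying an SWC compartment
#' type (1 soma, 2 axon, 3 dendrite), a position in micrometers and a radius.
#' The soma is the root; the z axis is oriented along cortical or retinal
#' depth. Nodes are stored topologically sorted (every parent precedes its
#' children).
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent
#'   (parent -1 for the root).
#' @param meta optional list of metadata (source file, dataset, label).
#' @return An object of class \code{morphology}.
#' @export
morphology <- function(nodes, meta = list()) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes)))
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  nodes <- nodes[, required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$type %in% c(1L, 2L, 3L)))
    stop("unsupported node type(s): ",
         paste(unique(nodes$type[!nodes$type %in% 1:3]), collapse = ", "),
         " (expected 1 soma, 2 axon, 3 dendrite)")
  if (any(nodes$radius < 0)) stop("negative radius")
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0L) stop("no root node (parent -1) found")
  if (length(roots) > 1L)
    stop("multiple roots (one tree per reconstruction expected): ids ",
         paste(nodes$id[roots], collapse = ", "))
  missing_parent <- setdiff(nodes$parent, c(-1L, nodes$id))
  if (length(missing_parent))
    stop("node(s) ", paste(nodes$id[nodes$parent %in% missing_parent], collapse = ", "),
         " reference missing parent id(s) ", paste(missing_parent, collapse = ", "))
  nodes <- topo_sort_nodes(nodes)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, meta = meta), class = "morphology")
}

# Sort nodes so parents precede children; detects cycles / disconnection.
topo_sort_nodes <- function(nodes) {
  n <- nrow(nodes)
  idx <- match(nodes$parent, nodes$id)        # NA for root
  children <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  order <- integer(n)
  root <- which(nodes$parent == -1L)
  queue <- root; pos <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    pos <- pos + 1L
    order[pos] <- v
    kids <- children[[as.character(v)]]
    if (length(kids)) queue <- c(queue, kids)
  }
  if (pos < n)
    stop("cycle or disconnected component detected (",
         n - pos, " unreachable node(s))")
  nodes[order, , drop = FALSE]
}

#' Parse SWC content into a morphology
#'
#' Accepts the plain 7-column SWC dialect: whitespace (space or tab)
#' delimited, comment lines starting with '#', one tree per file with the
#' root's parent encoded as -1. Ids need not be consecutive.
#'
#' @param text character vector of SWC lines, or a single string.
#' @param meta optional metadata list.
#' @return A \code{morphology}.
#' @export
parse_swc <- function(text, meta = list()) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  if (!length(text)) stop("no SWC data lines found")
  fields <- strsplit(text, "[ \t]+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop("malformed SWC line ", bad[1], ": expected 7 columns, got ",
         length(fields[[bad[1]]]))
  mat <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric field in SWC data")
  nodes <- data.frame(id = mat[, 1], type = mat[, 2], x = mat[, 3],
                      y = mat[, 4], z = mat[, 5], radius = mat[, 6],
                      parent = mat[, 7])
  morphology(nodes, meta)
}

#' Read a morphology from an SWC file
#' @param path file path.
#' @return A \code{morphology}.
#' @export
read_swc <- function(path) {
  m <- parse_swc(readLines(path, warn = FALSE))
  m$meta$file <- path
  m
}

#' Write a morphology to an SWC file
#'
#' Writes the standard 7-column format; output is byte-deterministic for a
#' given morphology.
#'
#' @param m a \code{morphology}.
#' @param path file path.
#' @export
write_swc <- function(m, path) {
  nd <- m$nodes
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

# ---- basic tree queries ------------------------------------------------

# list(parent_row, children (list per row), root, tips, branch_points,
#      n_children)
tree_structure <- function(m) {
  nd <- m$nodes
  n <- nrow(nd)
  parent_row <- match(nd$parent, nd$id)      # NA for root
  n_children <- tabulate(parent_row[!is.na(parent_row)], n)
  children <- vector("list", n)
  ord <- which(!is.na(parent_row))
  for (v in ord) {
    p <- parent_row[v]
    children[[p]] <- c(children[[p]], v)
  }
  list(parent_row = parent_row,
       children = children,
       n_children = n_children,
       root = which(is.na(parent_row)),
       tips = which(n_children == 0L),
       branch_points = which(n_children >= 2L))
}

edge_lengths <- function(m, ts = tree_structure(m)) {
  nd <- m$nodes
  p <- ts$parent_row
  len <- rep(NA_real_, nrow(nd))
  has <- !is.na(p)
  len[has] <- sqrt((nd$x[has] - nd$x[p[has]])^2 +
                   (nd$y[has] - nd$y[p[has]])^2 +
                   (nd$z[has] - nd$z[p[has]])^2)
  len
}

n_tips <- function(m) length(tree_structure(m)$tips)

total_length <- function(m) sum(edge_lengths(m), na.rm = TRUE)

soma_row <- function(m) {
  r <- which(m$nodes$parent == -1L)
  r[1]
}

#' @export
print.morphology <- function(x, ...) {
  ts <- tree_structure(x)
  cat("Neuron morphology: ", nrow(x$nodes), " nodes, ",
      length(ts$tips), " tips, ", length(ts$branch_points),
      " branch points\n", sep = "")
  tl <- total_length(x)
  cat(sprintf("  total neurite length %.1f um; types: %s\n", tl,
              paste(sprintf("%s=%d", c("soma", "axon", "dendrite")[sort(unique(x$nodes$type))],
                            table(x$nodes$type)), collapse = ", ")))
  if (!is.null(x$meta$label)) cat("  label:", x$meta$label, "\n")
  invisible(x)
}

#' @export
summary.morphology <- function(object, ...) {
  ts <- tree_structure(object)
  out <- list(n_nodes = nrow(object$nodes), n_tips = length(ts$tips),
              n_branch_points = length(ts$branch_points),
              total_length = total_length(object),
              extent = apply(object$nodes[, c("x", "y", "z")], 2, function(v) diff(range(v))))
  class(out) <- "summary.morphology"
  out
}

#' @export
print.summary.morphology <- function(x, ...) {
  cat(sprintf("nodes %d | tips %d | branch points %d | length %.1f um\n",
              x$n_nodes, x$n_tips, x$n_branch_points, x$total_length))
  cat(sprintf("extent (um): x %.1f, y %.1f, z %.1f\n",
              x$extent[1], x$extent[2], x$extent[3]))
  invisible(x)
}

#' Plot a 2D projection of a morphology
#' @param x a \code{morphology}.
#' @param plane one of "xy", "xz", "yz".
#' @param ... passed to \code{plot}.
#' @export
plot.morphology <- function(x, plane = "xz", ...) {
  ax <- strsplit(plane, "")[[1]]
  nd <- x$nodes
  ts <- tree_structure(x)
  p <- ts$parent_row
  has <- which(!is.na(p))
  graphics::plot(nd[[ax[1]]], nd[[ax[2]]], type = "n", xlab = ax[1],
                 ylab = ax[2], asp = 1, ...)
  cols <- c("1" = "black", "2" = "#7fbf7f", "3" = "#1b5e20")
  graphics::segments(nd[[ax[1]]][p[has]], nd[[ax[2]]][p[has]],
                     nd[[ax[1]]][has], nd[[ax[2]]][has],
                     col = cols[as.character(nd$type[has])])
  graphics::points(nd[[ax[1]]][ts$root], nd[[ax[2]]][ts$root], pch = 16)
  invisible(x)
}

# Validate invariants; used by tests and after preprocessing steps.
validate_morphology <- function(m) {
  stopifnot(inherits(m, "morphology"))
  nd <- m$nodes
  stopifnot(sum(nd$parent == -1L) == 1L)
  p <- match(nd$parent, nd$id)
  stopifnot(all(is.na(p) | p < seq_len(nrow(nd))))  # topological order
  stopifnot(all(nd$radius >= 0))
  invisible(TRUE)
}
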