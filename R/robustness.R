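# Robustness to partial tracings: branch-order truncation and shuffled-label
# chance-level estimation.

#' Truncate a morphology by removing high-order branches
#'
#' Simulates a partial tracing: of the B branches (segments), the
#' \code{floor(fraction * B)} with the highest centrifugal branch order are
#' removed, together with their subtrees. Ties at the removal boundary are
#' broken by the greater path distance of the branch start from the soma,
#' then by the smaller start node id, so distal material is removed first and
#' removal sets are nested across fractions. At least one stem always
#' survives (the requested count is capped, with a message, if it would
#' remove the whole tree).
#'
#' @param m a preprocessed \code{morphology}.
#' @param fraction fraction of branches to remove, in [0, 1).
#' @return A valid truncated \code{morphology}.
#' @export
truncate_morphology <- function(m, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(m)
  ts <- tree_structure(m)
  segs <- segment_paths(m, ts)
  nd <- m$nodes
  elen <- edge_lengths(m, ts)
  pathd <- numeric(nrow(nd))
  for (v in seq_len(nrow(nd)))
    if (!is.na(ts$parent_row[v])) pathd[v] <- pathd[ts$parent_row[v]] + elen[v]
  is_bp <- ts$n_children >= 2L
  is_bp[ts$root] <- FALSE
  ord <- integer(nrow(nd))
  for (v in seq_len(nrow(nd))) {
    p <- ts$parent_row[v]
    if (!is.na(p)) ord[v] <- ord[p] + as.integer(is_bp[p])
  }
  seg_order <- vapply(segs, function(path) ord[path[2L]], 0L)
  seg_start_dist <- vapply(segs, function(path) pathd[path[1L]], 0)
  seg_start_id <- vapply(segs, function(path) nd$id[path[1L]], 0L)
  B <- length(segs)
  k <- floor(fraction * B)
  if (k >= B) {
    message("truncation capped to keep at least one stem")
    k <- B - 1L
  }
  if (k == 0L) return(m)
  ranking <- order(-seg_order, -seg_start_dist, seg_start_id)
  drop_rows <- unique(unlist(lapply(ranking[seq_len(k)], function(i)
    segs[[i]][-1L])))
  keep <- setdiff(seq_len(nrow(nd)), drop_rows)
  morphology(nd[keep, , drop = FALSE], m$meta)
}

#' Truncation robustness experiment
#'
#' For every truncation fraction, all cells are truncated, re-featurized
#' under each requested representation, and every pair of cell types is
#' classified with the elastic-net pipeline. Cells whose featurization fails
#' at some truncation level (e.g. an emptied modality) are excluded from that
#' level with a warning.
#'
#' @param morphologies named list of preprocessed \code{morphology} objects.
#' @param labels factor of cell-type labels aligned with
#'   \code{morphologies}.
#' @param representations character vector of representation specs
#'   understood by \code{\link{featurize_population}}.
#' @param fractions truncation fractions, default \code{seq(0.1, 0.9, 0.1)}.
#' @param config a \code{\link{cv_config}}.
#' @param modality compartment modality for featurization.
#' @return data.frame with one row per fraction x representation x pair and
#'   the mean cross-validated metrics.
#' @export
truncation_experiment <- function(morphologies, labels, representations,
                                  fractions = seq(0.1, 0.9, by = 0.1),
                                  config = cv_config(), modality = "full") {
  labels <- as.factor(labels)
  pairs <- utils::combn(levels(labels), 2, simplify = FALSE)
  out <- list()
  for (f in c(0, fractions)) {
    trunc <- lapply(morphologies, truncate_morphology, fraction = f)
    for (rep_spec in representations) {
      fm <- featurize_population(trunc, rep_spec, modality = modality)
      ok <- apply(is.finite(fm$x), 1, all)
      if (!all(ok))
        warning(sum(!ok), " cell(s) excluded at fraction ", f, call. = FALSE)
      for (pr in pairs) {
        sel <- ok & labels %in% pr
        res <- fit_binary(fm$x[sel, , drop = FALSE], droplevels(labels[sel]),
                          config = config, preprocess = fm$preprocess)
        out[[length(out) + 1L]] <- data.frame(
          fraction = f, representation = rep_spec,
          pair = paste(pr, collapse = "|"),
          log_loss = res$means[["log_loss"]],
          accuracy = res$means[["accuracy"]],
          macro_f1 = res$means[["macro_f1"]],
          mcc = res$means[["mcc"]])
      }
    }
  }
  do.call(rbind, out)
}

#' Shuffled-label chance-level distribution
#'
#' Runs the identical cross-validation pipeline on label permutations to
#' obtain the empirical chance-level distribution of the log-loss; its mean
#' should agree with the theoretical ln(2) for balanced binary problems.
#'
#' @inheritParams fit_binary
#' @param n_shuffles number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list(values, mean, min, max) of mean log-losses per shuffle.
#' @export
shuffle_null <- function(x, y, config = cv_config(), n_shuffles = 10L,
                         seed = 1L, preprocess = "pca") {
  y <- droplevels(as.factor(y))
  perms <- with_seed(seed, replicate(n_shuffles, sample(y), simplify = FALSE))
  vals <- vapply(perms, function(yp)
    fit_binary(x, yp, config = config, preprocess = preprocess)$means[["log_loss"]],
    0)
  list(values = vals, mean = mean(vals), min = min(vals), max = max(vals))
}
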