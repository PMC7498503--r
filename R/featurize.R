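# Population-level featurization: one representation spec -> one
# cells x features matrix, with dataset-level normalization (density-map
# ranges, distribution bin maxima, persistence-image rectangles) fitted on
# the same population.

#' Featurize a population of morphologies
#'
#' Representation specs:
#' \itemize{
#'   \item \code{"density_x"}, \code{"density_y"}, \code{"density_z"},
#'     \code{"density_xy"}, \code{"density_xz"}, \code{"density_yz"} --
#'     smoothed neurite density maps (100 or 10,000 features);
#'   \item \code{"morphometrics"} -- the 24 morphometric statistics;
#'   \item \code{"dist:<name>"} -- one of the 17 one-dimensional or six
#'     two-dimensional morphometric distributions;
#'   \item \code{"persistence2d:<filter>"}, \code{"persistence1d:<filter>"}
#'     -- Gaussian persistence images (10,000 or 100 features) under one of
#'     the four filter functions.
#' }
#' Dataset-level constants (normalization ranges, bin maxima, persistence
#' rectangles) are fitted on the supplied population unless given.
#'
#' @param morphologies named list of preprocessed \code{morphology} objects.
#' @param representation a representation spec string.
#' @param modality "full", "axon" or "dendrite".
#' @param density_spacing skeleton sampling spacing for density maps (um).
#' @param ranges optional fixed \code{normalization_ranges} for density maps.
#' @param edges optional fixed \code{\link{dataset_edges}} list.
#' @param seed seed for the randomized distribution vectors.
#' @return list(x = numeric matrix (cells x features), representation,
#'   modality, preprocess = suggested preprocessing ("pca" or "zscore")).
#' @export
featurize_population <- function(morphologies, representation,
                                 modality = c("full", "axon", "dendrite"),
                                 density_spacing = 0.025, ranges = NULL,
                                 edges = NULL, seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(length(morphologies) >= 1L)
  preprocess <- "pca"

  if (grepl("^density_", representation)) {
    axis_spec <- sub("^density_", "", representation)
    clouds <- lapply(morphologies, sample_points, spacing = density_spacing,
                     modality = modality)
    if (is.null(ranges)) ranges <- fit_ranges(clouds)
    rows <- lapply(clouds, function(cl)
      flatten_density_map(density_map(cl, ranges, axis_spec)))
  } else if (representation == "morphometrics") {
    geoms <- lapply(morphologies, geometry_tables, modality = modality)
    stat_rows <- lapply(geoms, compute_statistics)
    stat_names <- names(stat_rows[[1]])
    rows <- lapply(stat_rows, as.numeric)
    preprocess <- "zscore"
  } else if (grepl("^dist:", representation)) {
    name <- sub("^dist:", "", representation)
    geoms <- lapply(morphologies, geometry_tables, modality = modality)
    if (is.null(edges)) edges <- dataset_edges(geoms)
    if (name %in% dist_2d_names) {
      rows <- lapply(geoms, function(g) distribution_2d(g, name, edges)$values)
    } else {
      rows <- lapply(seq_along(geoms), function(i)
        distribution_1d(geoms[[i]], name, edges,
                        seed = derive_seed(seed, i))$values)
    }
  } else if (grepl("^persistence[12]d:", representation)) {
    two_d <- grepl("^persistence2d:", representation)
    filter <- sub("^persistence[12]d:", "", representation)
    diags <- lapply(morphologies, compute_diagram, filter = filter,
                    modality = modality)
    max_birth <- max(vapply(diags, function(d) max(d$birth), 0))
    max_death <- max(vapply(diags, function(d) max(d$death), 0))
    if (max_birth <= 0) max_birth <- 1
    if (max_death <= 0) max_death <- max_birth
    rows <- lapply(diags, function(d) {
      if (two_d)
        flatten_persistence_image(persistence_image_2d(d, max_birth, max_death))
      else persistence_image_1d(d, max_birth)
    })
  } else {
    stop("unknown representation spec: ", representation)
  }

  lens <- unique(lengths(rows))
  if (length(lens) != 1L)
    stop("inconsistent feature lengths within representation ", representation)
  x <- do.call(rbind, rows)
  rownames(x) <- names(morphologies)
  if (representation == "morphometrics") colnames(x) <- stat_names
  list(x = x, representation = representation, modality = modality,
       preprocess = preprocess)
}
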