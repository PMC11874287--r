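#' Analysis parameters
#'
#' Single home for every numeric parameter of the pipeline. Defaults are the
#' published operating point of the method: each cell's 40 nearest neighbours
#' within 75 um define the neighbourhood graph; a 15 um expansion defines
#' close contact; immune cells are clustered into 3 neighbourhoods; the
#' immunotype classifier uses a CD8 density cutoff of 200 cells/mm2 and a
#' parenchymal:stromal ratio cutoff of 0.5 (primary version) or 0.6 (revised
#' version); permutation calls use 5% tails; marker intensities are arcsinh
#' transformed with cofactor 0.5.
#'
#' @param knn_k maximum number of nearest neighbours per cell.
#' @param knn_max_dist neighbour search radius, um.
#' @param expansion_dist per-cell dilation for the contact graph, um.
#' @param n_centres number of immune neighbourhoods (k-means centres).
#' @param density_cutoff CD8 density separating depleted from infiltrated
#'   ROIs, cells/mm2.
#' @param ratio_cutoff named vector with the parenchymal:stromal ratio
#'   cutoffs of the `primary` and `revised` classifier versions.
#' @param tail_fraction per-tail significance fraction of the permutation
#'   interaction test.
#' @param n_permutations number of label permutations per ROI.
#' @param arcsinh_cofactor cofactor of the arcsinh intensity transform.
#' @param cell_radius default disc radius of a cell, um, used by the
#'   expansion-contact graph when no per-cell area is available.
#' @param rng_seed integer seed.
#' @return object of class `analysis_params` (a validated list).
#' @export
analysis_params <- function(knn_k = 40L,
                            knn_max_dist = 75,
                            expansion_dist = 15,
                            n_centres = 3L,
                            density_cutoff = 200,
                            ratio_cutoff = c(primary = 0.5, revised = 0.6),
                            tail_fraction = 0.05,
                            n_permutations = 1000L,
                            arcsinh_cofactor = 0.5,
                            cell_radius = 5,
                            rng_seed = 1L) {
  p <- list(knn_k = as.integer(knn_k), knn_max_dist = knn_max_dist,
            expansion_dist = expansion_dist, n_centres = as.integer(n_centres),
            density_cutoff = density_cutoff, ratio_cutoff = ratio_cutoff,
            tail_fraction = tail_fraction,
            n_permutations = as.integer(n_permutations),
            arcsinh_cofactor = arcsinh_cofactor, cell_radius = cell_radius,
            rng_seed = as.integer(rng_seed))
  num <- c(p$knn_k, p$knn_max_dist, p$expansion_dist, p$n_centres,
           p$density_cutoff, p$ratio_cutoff, p$n_permutations,
           p$arcsinh_cofactor, p$cell_radius)
  if (any(!is.finite(num)) || any(num <= 0))
    stop_("all analysis parameters must be positive and finite")
  if (!all(c("primary", "revised") %in% names(p$ratio_cutoff)))
    stop_("ratio_cutoff must name 'primary' and 'revised' values")
  if (p$tail_fraction <= 0 || p$tail_fraction >= 0.5)
    stop_("tail_fraction must lie in (0, 0.5)")
  structure(p, class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm,
                paste(if (!is.null(names(v))) paste0(names(v), "=", v) else v,
                      collapse = ", ")))
  }
  invisible(x)
}
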