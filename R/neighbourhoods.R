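#' Default vocabulary and hub marker sets
#'
#' The default 23-type vocabulary mirrors a liver-tumour microenvironment
#' panel: tumour/parenchymal, stromal/vascular, and immune populations. The
#' three hub marker sets name the immune-neighbourhood architectures by
#' their enriched populations: a CD8/plasma-cell hub, a myeloid hub, and a
#' B-cell/CD4 hub.
#'
#' @return `default_type_vocabulary()`: character vector of 23 cell types;
#'   `default_immune_types()`: its immune subset; `default_marker_sets()`:
#'   named list of the three hub type-sets.
#' @export
default_type_vocabulary <- function() {
  c("Tumour", "Hepatocyte", "Cholangiocyte", "Endothelial", "LSEC",
    "Fibroblast", "HSC", "Smooth muscle", "CD8 T-cell", "CD4 T-cell",
    "Treg", "Tfh", "gd T-cell", "MAIT", "NK", "B cell", "Plasma cell",
    "Macrophage", "Kupffer cell", "Monocyte", "APC", "pDC", "Neutrophil")
}

#' @rdname default_type_vocabulary
#' @export
default_immune_types <- function() {
  c("CD8 T-cell", "CD4 T-cell", "Treg", "Tfh", "gd T-cell", "MAIT", "NK",
    "B cell", "Plasma cell", "Macrophage", "Kupffer cell", "Monocyte",
    "APC", "pDC", "Neutrophil")
}

#' @rdname default_type_vocabulary
#' @export
default_marker_sets <- function() {
  list("CD8-hub" = c("CD8 T-cell", "Plasma cell"),
       "myeloid-hub" = c("Macrophage", "Kupffer cell", "Monocyte", "APC",
                         "pDC", "Neutrophil"),
       "B/CD4-hub" = c("B cell", "CD4 T-cell", "Treg", "Tfh"))
}

#' Detect immune neighbourhoods by k-means on spatial profiles
#'
#' Clusters immune cells into neighbourhoods from their spatial composition
#' profiles (see [neighbour_profile()]), pooled across all ROIs of a cohort
#' so the neighbourhood vocabulary is shared between patients. Clustering is
#' `stats::kmeans` run from `n_init` random restarts (initial centres drawn
#' from the distinct profile rows); the restart with the lowest total
#' within-cluster sum of squares wins. Deterministic given `seed`.
#'
#' @param profiles numeric matrix of per-cell composition profiles (rows:
#'   cells; rownames carry identities).
#' @param n_centres number of neighbourhoods (default 3).
#' @param seed integer RNG seed.
#' @param n_init number of random restarts.
#' @param iter_max k-means iteration cap.
#' @return object of class `neighbourhood_assignment`: `labels` (named
#'   integer vector 1..k), `centroids`, `tot_withinss`, `semantic_names`
#'   (filled by [label_neighbourhood_semantics()]), `params`.
#' @export
detect_neighbourhoods <- function(profiles, n_centres = 3L, seed = 1L,
                                  n_init = 10L, iter_max = 300L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < n_centres)
    stop_("fewer profiles (%d) than centres (%d)", nrow(profiles), n_centres)
  u <- unique(profiles)
  if (nrow(u) < n_centres)
    stop_("degenerate input: only %d distinct profiles for %d centres",
          nrow(u), n_centres)
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_init)) {
    centres0 <- u[sample.int(nrow(u), n_centres), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(profiles, centers = centres0,
                                     iter.max = iter_max)),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop_("k-means failed for every restart")
  structure(list(labels = setNames(best$cluster, rownames(profiles)),
                 centroids = best$centers,
                 tot_withinss = best$tot.withinss,
                 semantic_names = NULL,
                 params = list(n_centres = as.integer(n_centres),
                               seed = as.integer(seed),
                               n_init = as.integer(n_init),
                               iter_max = as.integer(iter_max))),
            class = "neighbourhood_assignment")
}

#' @export
print.neighbourhood_assignment <- function(x, ...) {
  cat(sprintf("neighbourhood_assignment: %d cells in %d neighbourhoods (seed %d)\n",
              length(x$labels), x$params$n_centres, x$params$seed))
  if (!is.null(x$semantic_names))
    cat("  semantics:", paste(names(x$semantic_names), "->",
                              x$semantic_names, collapse = "; "), "\n")
  invisible(x)
}

#' Name detected neighbourhoods by their enriched populations
#'
#' Maps each neighbourhood to the architecture whose marker type-set shows
#' the highest relative enrichment among its member cells (mean in-cluster
#' fraction of the set divided by its overall fraction). The mapping is made
#' bijective by greedy assignment on descending enrichment. Only defined for
#' exactly as many neighbourhoods as marker sets (3 by default); otherwise
#' the raw labels are retained and the assignment is returned unchanged.
#'
#' @param assignment a `neighbourhood_assignment`.
#' @param table the `cell_table` the profiles came from.
#' @param marker_sets named list of cell-type sets defining the candidate
#'   architectures (default [default_marker_sets()]).
#' @return the assignment with `semantic_names` filled in: a named character
#'   vector mapping cluster index (as character) to architecture name.
#' @export
label_neighbourhood_semantics <- function(assignment, table,
                                          marker_sets = default_marker_sets()) {
  k <- assignment$params$n_centres
  if (k != length(marker_sets)) return(assignment)
  ids <- names(assignment$labels)
  roi <- sub("\\|.*$", "", ids)
  cid <- sub("^[^|]*\\|", "", ids)
  key <- paste(table$cells$roi_id, table$cells$cell_id)
  type <- table$cells$cell_type[match(paste(roi, cid), key)]
  if (anyNA(type))
    stop_("assignment contains cells absent from the table")
  enr <- matrix(NA_real_, k, length(marker_sets),
                dimnames = list(as.character(seq_len(k)), names(marker_sets)))
  for (s in seq_along(marker_sets)) {
    inset <- type %in% marker_sets[[s]]
    overall <- mean(inset)
    for (c in seq_len(k)) {
      frac <- mean(inset[assignment$labels == c])
      enr[c, s] <- if (overall > 0) frac / overall else 0
    }
  }
  if (length(unique(as.vector(enr))) == 1)
    stop_("unresolved semantics: identical enrichment for all mappings (%s)",
          paste(round(as.vector(enr), 3), collapse = ", "))
  sem <- setNames(rep(NA_character_, k), as.character(seq_len(k)))
  e <- enr
  for (step in seq_len(k)) {
    w <- which(e == max(e, na.rm = TRUE), arr.ind = TRUE)[1, , drop = TRUE]
    sem[rownames(e)[w["row"]]] <- colnames(e)[w["col"]]
    e <- e[-w["row"], -w["col"], drop = FALSE]
  }
  assignment$semantic_names <- sem
  assignment$enrichment <- enr
  assignment
}

#' Per-ROI neighbourhood densities
#'
#' Counts labelled cells per neighbourhood per ROI and divides by the
#' whole-ROI area in mm2. Neighbourhood densities sum exactly to the immune
#' cell density of the ROI.
#'
#' @param assignment a `neighbourhood_assignment` covering the cohort's
#'   immune cells.
#' @param table the `cell_table`.
#' @param areas per-ROI area lookup ([mask_areas()]); `NULL` falls back to
#'   `roi_meta$roi_area_um2`.
#' @param use_semantics name neighbourhoods by their semantics when
#'   available.
#' @return data.frame: `roi_id`, `patient_id`, `in_label`, `count`,
#'   `area_mm2`, `density`.
#' @export
in_density <- function(assignment, table, areas = NULL,
                       use_semantics = TRUE) {
  roi <- sub("\\|.*$", "", names(assignment$labels))
  k <- assignment$params$n_centres
  lab <- as.character(assignment$labels)
  if (use_semantics && !is.null(assignment$semantic_names))
    lab <- unname(assignment$semantic_names[lab])
  levels <- if (use_semantics && !is.null(assignment$semantic_names))
    unname(assignment$semantic_names[as.character(seq_len(k))])
  else as.character(seq_len(k))
  meta <- table$roi_meta
  out <- lapply(seq_len(nrow(meta)), function(r) {
    rid <- meta$roi_id[r]
    area <- if (!is.null(areas)) unname(areas[[rid]]["all"]) else
      meta$roi_area_um2[r] / 1e6
    if (is.na(area) || area <= 0)
      stop_("no positive area for ROI '%s'", rid)
    counts <- table(factor(lab[roi == rid], levels = levels))
    data.frame(roi_id = rid, patient_id = meta$patient_id[r],
               in_label = names(counts), count = as.integer(counts),
               area_mm2 = area, density = as.integer(counts) / area,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
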