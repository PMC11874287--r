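#' Spatial neighbour graphs
#'
#' Two neighbour relations are used downstream: a directed k-nearest-
#' neighbour graph capped at a maximum radius (neighbourhood detection), and
#' a symmetric expansion-contact graph in which cells count as neighbours
#' when their dilated boundaries touch (interaction testing).
#'
#' @name spatial_graph
NULL

new_spatial_graph <- function(roi_id, variant, edges, params) {
  rownames(edges) <- NULL
  structure(list(roi_id = roi_id, variant = variant, edges = edges,
                 params = params), class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph (%s) for ROI '%s': %d directed edges\n",
              x$variant, x$roi_id, nrow(x$edges)))
  invisible(x)
}

#' Build the k-nearest-neighbour-within-radius graph of one ROI
#'
#' For each cell, directed edges to its at most `k` nearest other cells by
#' Euclidean centroid distance, excluding neighbours beyond `max_dist`.
#' Distance ties at the k-th neighbour are broken towards the smaller
#' `cell_id` so the graph is deterministic across platforms. Duplicate
#' coordinates are allowed (distance-0 neighbours rank first).
#'
#' @param cells data.frame of one ROI's cells with `cell_id`, `x`, `y` (e.g.
#'   from [roi_cells()]).
#' @param k maximum out-degree (default 40).
#' @param max_dist neighbour radius in um (default 75).
#' @param roi_id recorded in the graph.
#' @return a `spatial_graph` with `variant = "knn"`; edges have columns
#'   `from`, `to`, `dist`.
#' @export
build_knn_graph <- function(cells, k = 40L, max_dist = 75,
                            roi_id = cells$roi_id[1]) {
  if (k < 1 || max_dist <= 0) stop_("k must be >= 1 and max_dist > 0")
  n <- nrow(cells)
  empty <- data.frame(from = character(), to = character(), dist = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(n) || n <= 1)
    return(new_spatial_graph(roi_id %||% NA_character_, "knn", empty,
                             list(k = k, max_dist = max_dist)))
  ids <- cells$cell_id
  x <- cells$x; y <- cells$y
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1024))
  parts <- lapply(chunks, function(rows) {
    d <- dist_rows(x[rows], y[rows], x, y)
    res <- vector("list", length(rows))
    for (r in seq_along(rows)) {
      i <- rows[r]
      dr <- d[r, ]
      dr[i] <- Inf
      cand <- which(dr <= max_dist)
      if (!length(cand)) next
      ord <- cand[order(dr[cand], ids[cand])]
      sel <- ord[seq_len(min(k, length(ord)))]
      res[[r]] <- data.frame(from = ids[i], to = ids[sel], dist = dr[sel],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  edges <- do.call(rbind, parts)
  if (is.null(edges)) edges <- empty
  new_spatial_graph(roi_id %||% NA_character_, "knn", edges,
                    list(k = k, max_dist = max_dist))
}

#' Build the expansion-contact graph of one ROI
#'
#' Cells are modelled as discs (radius from `radii`, or `sqrt(area/pi)` when
#' an `area_um2` column is present). In `"disc"` mode (default) two cells are
#' neighbours when, after dilating both discs by `expansion`, they touch:
#' `dist - r_i - r_j <= 2 * expansion`. In `"centroid"` mode the rule is a
#' plain centroid-distance threshold `dist <= expansion`, for compatibility
#' with tools that define expansion that way. The relation is symmetric and
#' irreflexive; both edge directions are stored.
#'
#' @param cells data.frame of one ROI's cells (`cell_id`, `x`, `y`, optional
#'   `area_um2`).
#' @param expansion dilation distance per cell, um (default 15).
#' @param radii per-cell disc radius in um, or a scalar default (5 um);
#'   ignored when `cells$area_um2` exists or in centroid mode.
#' @param mode `"disc"` or `"centroid"`.
#' @param roi_id recorded in the graph.
#' @return a `spatial_graph` with `variant = "expansion"`; edges have
#'   columns `from`, `to`, `dist`, `gap` (boundary-to-boundary distance).
#' @export
build_expansion_graph <- function(cells, expansion = 15, radii = 5,
                                  mode = c("disc", "centroid"),
                                  roi_id = cells$roi_id[1]) {
  mode <- match.arg(mode)
  if (expansion <= 0) stop_("expansion must be positive")
  n <- nrow(cells)
  empty <- data.frame(from = character(), to = character(), dist = numeric(),
                      gap = numeric(), stringsAsFactors = FALSE)
  params <- list(expansion = expansion, mode = mode)
  if (is.null(n) || n <= 1)
    return(new_spatial_graph(roi_id %||% NA_character_, "expansion", empty,
                             params))
  if (!is.null(cells$area_um2)) radii <- sqrt(cells$area_um2 / pi)
  if (any(radii < 0)) stop_("cell radii must be nonnegative")
  r <- rep_len(radii, n)
  ids <- cells$cell_id
  x <- cells$x; y <- cells$y
  tol <- 1e-9
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 1024))
  parts <- lapply(chunks, function(rows) {
    d <- dist_rows(x[rows], y[rows], x, y)
    gap <- d - outer(r[rows], r, "+")
    linked <- if (mode == "disc") gap <= 2 * expansion + tol
              else d <= expansion + tol
    # keep i < j only; mirrored below
    linked <- linked & outer(rows, seq_len(n), "<")
    w <- which(linked, arr.ind = TRUE)
    if (!nrow(w)) return(NULL)
    data.frame(from = ids[rows[w[, 1]]], to = ids[w[, 2]],
               dist = d[w], gap = gap[w], stringsAsFactors = FALSE)
  })
  half <- do.call(rbind, parts)
  edges <- if (is.null(half)) empty else {
    rbind(half, data.frame(from = half$to, to = half$from, dist = half$dist,
                           gap = half$gap, stringsAsFactors = FALSE))
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  new_spatial_graph(roi_id %||% NA_character_, "expansion", edges, params)
}

#' Spatial composition profile of each immune cell
#'
#' For every immune cell of the graph's ROI, the composition of its graph
#' neighbours restricted to immune cells: the fraction (or count) of each
#' immune type among them. Isolated immune cells get a zero vector; fraction
#' rows otherwise sum to 1. These profiles are the clustering features for
#' immune-neighbourhood detection.
#'
#' @param graph a `spatial_graph` (the kNN variant feeds neighbourhood
#'   detection).
#' @param table the matching `cell_table`.
#' @param immune_types immune type vocabulary (default: the table's).
#' @param mode `"fraction"` (default) or `"count"`.
#' @return numeric matrix, one row per immune cell (rownames
#'   `"<roi>|<cell_id>"`), one column per immune type.
#' @export
neighbour_profile <- function(graph, table, immune_types = NULL,
                              mode = c("fraction", "count")) {
  mode <- match.arg(mode)
  immune_types <- immune_types %||% table$immune_types
  unknown <- setdiff(immune_types, table$type_vocabulary)
  if (length(unknown))
    stop_("immune type(s) outside vocabulary: %s",
          paste(unknown, collapse = ", "))
  cells <- roi_cells(table, graph$roi_id)
  type_of <- setNames(cells$cell_type, cells$cell_id)
  immune_ids <- cells$cell_id[cells$cell_type %in% immune_types]
  prof <- matrix(0, nrow = length(immune_ids), ncol = length(immune_types),
                 dimnames = list(paste0(graph$roi_id, "|", immune_ids),
                                 immune_types))
  e <- graph$edges
  keep <- type_of[e$from] %in% immune_types & type_of[e$to] %in% immune_types
  e <- e[keep, , drop = FALSE]
  if (nrow(e)) {
    counts <- table(factor(e$from, levels = immune_ids),
                    factor(type_of[e$to], levels = immune_types))
    counts <- matrix(counts, nrow = length(immune_ids))
    if (mode == "fraction") {
      tot <- rowSums(counts)
      counts <- counts / ifelse(tot > 0, tot, 1)
    }
    prof[] <- counts  # rows already follow immune_ids order
  }
  prof
}
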