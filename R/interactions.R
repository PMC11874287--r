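# Resolve a subset selector to a logical membership vector over one ROI's
# cells. A selector is either a cell type from the vocabulary or a subset
# flag present somewhere in the table.
subset_membership <- function(cells, table, sel) {
  if (sel %in% table$type_vocabulary)
    return(cells$cell_type == sel)
  if (any(has_flag(table$cells$subsets, sel)))
    return(has_flag(cells$subsets, sel))
  stop_("unknown subset '%s': not a cell type or subset flag", sel)
}

#' Directional interaction score between two cell subsets
#'
#' For each cell of subset A the number of its graph neighbours belonging to
#' subset B is counted. The `histocat` method divides the total by the
#' number of A cells that have at least one B neighbour; the `classic`
#' method divides by the number of A cells in the ROI. The score is
#' directional (A towards B) and undefined (`NA`) when its denominator is 0.
#'
#' @param graph a `spatial_graph` (typically the expansion-contact variant).
#' @param table the matching `cell_table`.
#' @param A,B subset selectors: a cell type or a subset flag.
#' @param method `"histocat"` (default) or `"classic"`.
#' @return single numeric score, `NA` if undefined.
#' @export
interaction_score <- function(graph, table, A, B,
                              method = c("histocat", "classic")) {
  method <- match.arg(method)
  cells <- roi_cells(table, graph$roi_id)
  memA <- subset_membership(cells, table, A)
  memB <- subset_membership(cells, table, B)
  e <- graph$edges
  ef <- match(e$from, cells$cell_id)
  et <- match(e$to, cells$cell_id)
  score_edges(memA, memB, ef, et, method)
}

# Core score computation on integer edge endpoints; shared with the
# permutation loop.
score_edges <- function(memA, memB, ef, et, method) {
  sel <- memA[ef] & memB[et]
  total <- sum(sel)
  denom <- if (method == "histocat") length(unique(ef[sel])) else sum(memA)
  if (denom == 0) NA_real_ else total / denom
}

#' Permutation test for cell-cell interaction and avoidance
#'
#' Tests, per ROI, whether subset A sits next to subset B more (interaction)
#' or less (avoidance) often than expected under complete spatial
#' independence of labels and positions. The null is built by permuting the
#' cells' label sets over the fixed graph (equivalent to randomising cell
#' localisations on the image, at a fraction of the cost). The observed
#' score's percentile in the null uses mid-rank tie handling,
#' `(#null < obs + 0.5 #null == obs + 0.5) / (n_perm + 1)`; a score in the
#' highest or lowest `tail_fraction` of the null is called a significant
#' interaction or avoidance. Null scores whose denominator is 0 (no A-B
#' contact at all) rank below every defined score. Calls are per ROI; no
#' multiplicity correction is applied at this stage.
#'
#' @param graph a `spatial_graph` (expansion-contact variant).
#' @param table the matching `cell_table`.
#' @param pairs list of `c(A, B)` selector pairs.
#' @param n_perm number of label permutations (default 1000).
#' @param tail_fraction per-tail call fraction (default 0.05).
#' @param seed integer RNG seed.
#' @param method score method, see [interaction_score()].
#' @param stratify_by_compartment when `TRUE`, labels are shuffled only
#'   within each compartment, preserving compartment composition under the
#'   null.
#' @return data.frame with one row per pair: `roi_id`, `from_subset`,
#'   `to_subset`, `observed`, `null_percentile`, `call` (one of
#'   `interaction`, `avoidance`, `ns`, `undefined`), `n_permutations`.
#' @export
permutation_interaction_test <- function(graph, table, pairs,
                                         n_perm = 1000L,
                                         tail_fraction = 0.05,
                                         seed = 1L,
                                         method = c("histocat", "classic"),
                                         stratify_by_compartment = FALSE) {
  method <- match.arg(method)
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop_("tail_fraction must lie in (0, 0.5)")
  if (is.numeric(pairs) || is.character(pairs)) pairs <- list(pairs)
  cells <- roi_cells(table, graph$roi_id)
  n <- nrow(cells)
  e <- graph$edges
  ef <- match(e$from, cells$cell_id)
  et <- match(e$to, cells$cell_id)
  sels <- unique(unlist(pairs))
  mem <- lapply(setNames(sels, sels), function(s)
    subset_membership(cells, table, s))
  obs <- vapply(pairs, function(p)
    score_edges(mem[[p[1]]], mem[[p[2]]], ef, et, method), numeric(1))
  strata <- if (stratify_by_compartment) cells$compartment else
    rep("all", n)
  strata_idx <- split(seq_len(n), strata)
  set.seed(seed)
  null <- matrix(NA_real_, n_perm, length(pairs))
  for (b in seq_len(n_perm)) {
    pm <- integer(n)
    for (ix in strata_idx) pm[ix] <- ix[sample.int(length(ix))]
    for (q in seq_along(pairs)) {
      p <- pairs[[q]]
      null[b, q] <- score_edges(mem[[p[1]]][pm], mem[[p[2]]][pm], ef, et,
                                method)
    }
  }
  records <- lapply(seq_along(pairs), function(q) {
    p <- pairs[[q]]
    o <- obs[q]
    if (is.na(o) || sum(mem[[p[1]]]) == 0 || sum(mem[[p[2]]]) == 0) {
      return(data.frame(roi_id = graph$roi_id, from_subset = p[1],
                        to_subset = p[2], observed = obs[q],
                        null_percentile = NA_real_, call = "undefined",
                        n_permutations = n_perm, stringsAsFactors = FALSE))
    }
    nl <- null[, q]
    nl[is.na(nl)] <- -Inf
    pc <- (sum(nl < o) + 0.5 * sum(nl == o) + 0.5) / (n_perm + 1)
    call <- if (pc >= 1 - tail_fraction) "interaction"
            else if (pc <= tail_fraction) "avoidance" else "ns"
    data.frame(roi_id = graph$roi_id, from_subset = p[1], to_subset = p[2],
               observed = obs[q], null_percentile = pc, call = call,
               n_permutations = n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Summarise interaction calls across ROIs
#'
#' Aggregates per-ROI interaction records into per-group counts and
#' fractions of ROIs with significant interaction and avoidance calls for
#' each directed subset pair — e.g. grouped by spatial immunotype.
#'
#' @param records row-bound [permutation_interaction_test()] outputs.
#' @param grouping named vector mapping `roi_id` to a group label, or a
#'   single label for all ROIs.
#' @return data.frame: `group`, `from_subset`, `to_subset`, `n_roi`,
#'   `n_interaction`, `n_avoidance`, `frac_interaction`, `frac_avoidance`.
#' @export
summarise_interactions <- function(records, grouping = "all") {
  if (!nrow(records))
    return(data.frame(group = character(), from_subset = character(),
                      to_subset = character(), n_roi = integer(),
                      n_interaction = integer(), n_avoidance = integer(),
                      frac_interaction = numeric(),
                      frac_avoidance = numeric(), stringsAsFactors = FALSE))
  grp <- if (length(grouping) == 1 && is.null(names(grouping)))
    rep(grouping, nrow(records)) else unname(grouping[records$roi_id])
  key <- interaction(grp, records$from_subset, records$to_subset,
                     drop = TRUE)
  out <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    r <- records[ix, , drop = FALSE]
    data.frame(group = grp[ix[1]], from_subset = r$from_subset[1],
               to_subset = r$to_subset[1], n_roi = nrow(r),
               n_interaction = sum(r$call == "interaction"),
               n_avoidance = sum(r$call == "avoidance"),
               frac_interaction = mean(r$call == "interaction"),
               frac_avoidance = mean(r$call == "avoidance"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interaction testing within one immune neighbourhood
#'
#' Subsets the ROI to the cells assigned to one neighbourhood, rebuilds the
#' expansion-contact graph on those cells, and runs the permutation test —
#' the within-neighbourhood variant of the interaction analysis.
#'
#' @param table the `cell_table`.
#' @param assignment a `neighbourhood_assignment`.
#' @param roi_id the ROI to test.
#' @param in_label neighbourhood label (semantic name or cluster index).
#' @param pairs,n_perm,tail_fraction,seed,method passed through.
#' @param expansion,radii passed to [build_expansion_graph()].
#' @return records as from [permutation_interaction_test()].
#' @export
test_interactions_within_in <- function(table, assignment, roi_id, in_label,
                                        pairs, n_perm = 1000L,
                                        tail_fraction = 0.05, seed = 1L,
                                        method = "histocat", expansion = 15,
                                        radii = 5) {
  lab <- as.character(assignment$labels)
  if (!is.null(assignment$semantic_names))
    lab <- ifelse(lab %in% names(assignment$semantic_names),
                  assignment$semantic_names[lab], lab)
  ids <- names(assignment$labels)
  sel_ids <- sub("^[^|]*\\|", "", ids[lab == in_label &
                                        sub("\\|.*$", "", ids) == roi_id])
  cells <- roi_cells(table, roi_id)
  cells <- cells[cells$cell_id %in% sel_ids, , drop = FALSE]
  sub_tbl <- table
  sub_tbl$cells <- cells
  g <- build_expansion_graph(cells, expansion = expansion, radii = radii,
                             roi_id = roi_id)
  permutation_interaction_test(g, sub_tbl, pairs, n_perm = n_perm,
                               tail_fraction = tail_fraction, seed = seed,
                               method = method)
}
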