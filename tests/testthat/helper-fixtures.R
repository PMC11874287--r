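# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as plain loops, independent of the package's
# vectorised implementations.

# Minimal cell table: cells at given coordinates/types in one ROI.
make_table <- function(x, y, cell_type, roi_id = "R1", patient_id = "P1",
                       subsets = "", area_um2 = 1e6,
                       vocabulary = NULL, immune = NULL) {
  cells <- data.frame(cell_id = sprintf("c%03d", seq_along(x)),
                      roi_id = roi_id, patient_id = patient_id,
                      x = x, y = y, cell_type = cell_type,
                      subsets = subsets, stringsAsFactors = FALSE)
  meta <- unique(cells[, c("roi_id", "patient_id")])
  meta$roi_kind <- "tumour"
  meta$roi_area_um2 <- area_um2
  meta$pixel_size_um <- 1
  cell_table(cells, roi_meta = meta,
             type_vocabulary = vocabulary %||% sort(unique(cell_type)),
             immune_types = immune %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) nearest-neighbour oracle: per cell, all others ordered by
# (distance, cell_id), truncated at k and max_dist.
brute_knn <- function(cells, k, max_dist) {
  n <- nrow(cells)
  out <- list()
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    cand <- setdiff(which(d <= max_dist), i)
    if (!length(cand)) next
    cand <- cand[order(d[cand], cells$cell_id[cand])]
    cand <- cand[seq_len(min(k, length(cand)))]
    out[[length(out) + 1]] <- data.frame(from = cells$cell_id[i],
                                         to = cells$cell_id[cand],
                                         stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(from = character(), to = character()))
  do.call(rbind, out)
}

edge_key <- function(e) sort(paste(e$from, e$to))

# Exact permutation percentile for a two-type labelling on a fixed edge
# list: enumerates every placement of the A labels, scores each with an
# explicit loop, and applies the mid-rank percentile formula.
exhaustive_percentile <- function(cells_xy, labels, A, B, expansion = 15,
                                  radius = 5) {
  n <- nrow(cells_xy)
  touching <- function(i, j) {
    d <- sqrt((cells_xy$x[i] - cells_xy$x[j])^2 +
                (cells_xy$y[i] - cells_xy$y[j])^2)
    d - 2 * radius <= 2 * expansion + 1e-9
  }
  score_for <- function(lab) {
    total <- 0; with_b <- 0
    for (i in which(lab == A)) {
      nb <- 0
      for (j in setdiff(seq_len(n), i))
        if (lab[j] == B && touching(i, j)) nb <- nb + 1
      total <- total + nb
      if (nb > 0) with_b <- with_b + 1
    }
    if (with_b == 0) -Inf else total / with_b
  }
  obs <- score_for(labels)
  nA <- sum(labels == A)
  combos <- utils::combn(n, nA)
  null <- apply(combos, 2, function(ix) {
    lab <- rep(B, n); lab[ix] <- A
    score_for(lab)
  })
  if (is.infinite(obs)) return(NA_real_)
  (sum(null < obs) + 0.5 * sum(null == obs) + 0.5) / (length(null) + 1)
}

# Product-limit oracle: hand-rolled loop over distinct event times.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank oracle: observed-minus-expected and hypergeometric
# variance summed over event times.
logrank_oracle <- function(time, event, group) {
  lev <- unique(group)
  stopifnot(length(lev) == 2)
  ts <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == lev[1])
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == lev[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# One planted-architecture ROI: three vertical bands, each dominated by one
# hub's populations, plus a thin non-immune backdrop.
planted_roi <- function(n_per_band = 250, width = 900, seed = 1) {
  set.seed(seed)
  bands <- list(
    c("CD8 T-cell", "Plasma cell"),
    c("Macrophage", "APC", "Monocyte"),
    c("B cell", "CD4 T-cell", "Treg"))
  rows <- lapply(1:3, function(b) {
    types <- sample(bands[[b]], n_per_band, replace = TRUE)
    data.frame(x = runif(n_per_band, (b - 1) * width / 3, b * width / 3),
               y = runif(n_per_band, 0, 300), cell_type = types,
               band = b, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  tbl <- make_table(d$x, d$y, d$cell_type, area_um2 = width * 300,
                    vocabulary = default_type_vocabulary(),
                    immune = default_immune_types())
  list(table = tbl, band = d$band)
}
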