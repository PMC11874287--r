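#' Map cells into microanatomical compartments
#'
#' Sets every cell's `compartment` field to the compartment of the mask pixel
#' containing its centroid (floor lookup; a centroid exactly on the right or
#' bottom raster edge belongs to the last pixel). Cells on background pixels
#' or outside the raster are set to `"unassigned"`; out-of-bounds cells are
#' additionally reported in the `assignment_issues` attribute rather than
#' dropped.
#'
#' @param table a [cell_table()].
#' @param masks a single `region_mask` or a list of them; matched to ROIs by
#'   their `roi_id`.
#' @return the `cell_table` with compartments filled in; attribute
#'   `assignment_issues` holds a data.frame of out-of-bounds cells.
#' @export
assign_compartments <- function(table, masks) {
  if (inherits(masks, "region_mask")) masks <- list(masks)
  names(masks) <- vapply(masks, function(m) m$roi_id, character(1))
  cells <- table$cells
  issues <- list()
  for (roi in unique(cells$roi_id)) {
    m <- masks[[roi]]
    if (is.null(m)) stop_("no mask supplied for ROI '%s'", roi)
    idx <- which(cells$roi_id == roi)
    px <- m$pixel_size_um
    nr <- nrow(m$labels); nc <- ncol(m$labels)
    j <- floor(cells$x[idx] / px)
    i <- floor(cells$y[idx] / px)
    # right/bottom edge belongs to the last pixel
    j[cells$x[idx] == nc * px] <- nc - 1
    i[cells$y[idx] == nr * px] <- nr - 1
    oob <- j < 0 | i < 0 | j > nc - 1 | i > nr - 1
    comp <- rep("unassigned", length(idx))
    if (any(!oob)) {
      lab <- m$labels[cbind(i[!oob] + 1, j[!oob] + 1)]
      cc <- m$semantics[as.character(lab)]
      cc[lab == 0L] <- "unassigned"
      comp[!oob] <- cc
    }
    cells$compartment[idx] <- comp
    if (any(oob))
      issues[[roi]] <- data.frame(roi_id = roi,
                                  cell_id = cells$cell_id[idx][oob],
                                  x = cells$x[idx][oob],
                                  y = cells$y[idx][oob],
                                  issue = "out_of_bounds",
                                  stringsAsFactors = FALSE)
  }
  table$cells <- cells
  iss <- if (length(issues)) do.call(rbind, issues) else
    data.frame(roi_id = character(), cell_id = character(), x = numeric(),
               y = numeric(), issue = character(), stringsAsFactors = FALSE)
  rownames(iss) <- NULL
  attr(table, "assignment_issues") <- iss
  if (nrow(iss))
    message(sprintf("assign_compartments: %d cell(s) outside raster bounds left unassigned",
                    nrow(iss)))
  table
}

#' Compartment areas of a mask
#'
#' Area is pixel count times the squared pixel size, reported in mm2
#' (1 pixel = 1 um2 at the default resolution). Background (label 0) is
#' excluded from compartment totals and reported in the `background_mm2`
#' attribute; the `total_mm2` attribute is the full raster area.
#'
#' @param mask a `region_mask`.
#' @return named numeric vector of areas in mm2, one entry per compartment in
#'   the mask semantics (0 when absent from the raster).
#' @export
compartment_areas <- function(mask) {
  px2 <- mask$pixel_size_um^2
  counts <- table(factor(as.vector(mask$labels),
                         levels = c(0L, as.integer(names(mask$semantics)))))
  out <- numeric(0)
  for (comp in unique(unname(mask$semantics))) {
    labs <- names(mask$semantics)[mask$semantics == comp]
    out[comp] <- sum(counts[labs]) * px2 / 1e6
  }
  attr(out, "background_mm2") <- unname(counts["0"]) * px2 / 1e6
  attr(out, "total_mm2") <- length(mask$labels) * px2 / 1e6
  out
}

#' Per-ROI area lookup from masks
#'
#' Convenience wrapper building, for each mask, the compartment areas plus an
#' `"all"` entry equal to the full raster area — the shape expected by
#' [cell_density()].
#'
#' @param masks a `region_mask` or list of them.
#' @return named list (by roi_id) of named area vectors in mm2.
#' @export
mask_areas <- function(masks) {
  if (inherits(masks, "region_mask")) masks <- list(masks)
  out <- lapply(masks, function(m) {
    a <- compartment_areas(m)
    c(a, all = attr(a, "total_mm2"))
  })
  names(out) <- vapply(masks, function(m) m$roi_id, character(1))
  out
}

#' Compartment-resolved cell densities
#'
#' Counts the selected cells per ROI and divides by the relevant area:
#' the whole-ROI area for `compartment = "all"`, else the compartment's mask
#' area. Densities are in cells/mm2; a zero count gives density 0.
#'
#' @param table a `cell_table` (compartments must be assigned when
#'   `compartment != "all"`).
#' @param cell_types character vector of cell types to count (`NULL` = all).
#' @param subset optional subset flag; only cells carrying it are counted.
#' @param compartment compartment name or `"all"`.
#' @param areas per-ROI area lookup from [mask_areas()]; when `NULL`,
#'   whole-ROI areas are taken from `roi_meta$roi_area_um2`.
#' @param selector label recorded in the output (defaults to a readable
#'   description of `cell_types`/`subset`).
#' @return data.frame with one row per ROI: `roi_id`, `patient_id`,
#'   `selector`, `compartment`, `count`, `area_mm2`, `density`, `flag`.
#' @export
cell_density <- function(table, cell_types = NULL, subset = NULL,
                         compartment = "all", areas = NULL,
                         selector = NULL) {
  if (!is.null(cell_types)) {
    unknown <- setdiff(cell_types, table$type_vocabulary)
    if (length(unknown))
      stop_("unknown cell type(s): %s", paste(unknown, collapse = ", "))
  }
  selector <- selector %||% paste(c(cell_types %||% "all-cells", subset),
                                  collapse = "+")
  cells <- table$cells
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(cell_types)) keep <- keep & cells$cell_type %in% cell_types
  if (!is.null(subset)) keep <- keep & has_flag(cells$subsets, subset)
  if (compartment != "all") keep <- keep & cells$compartment == compartment
  meta <- table$roi_meta
  out <- lapply(seq_len(nrow(meta)), function(r) {
    roi <- meta$roi_id[r]
    count <- sum(keep & cells$roi_id == roi)
    area <- if (!is.null(areas)) {
      a <- areas[[roi]]
      if (is.null(a) || !compartment %in% names(a))
        stop_("no area for compartment '%s' in ROI '%s'", compartment, roi)
      unname(a[compartment])
    } else {
      if (compartment != "all")
        stop_("compartment-level densities need mask areas; pass `areas`")
      if (is.na(meta$roi_area_um2[r]))
        stop_("roi_area_um2 missing for ROI '%s'; pass `areas` or set it", roi)
      meta$roi_area_um2[r] / 1e6
    }
    flag <- ""
    if (area <= 0) {
      if (count > 0)
        stop_("ROI '%s': %d cells counted in zero-area compartment '%s'",
              roi, count, compartment)
      density <- NA_real_
      flag <- "undefined_area"
    } else density <- count / area
    data.frame(roi_id = roi, patient_id = meta$patient_id[r],
               selector = selector, compartment = compartment,
               count = count, area_mm2 = area, density = density,
               flag = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average ROI-level records per patient
#'
#' When a patient contributed more than one ROI, the per-patient value is the
#' unweighted arithmetic mean across that patient's ROIs.
#'
#' @param records data.frame of ROI-level records with `patient_id`,
#'   `selector`, `compartment`, `density` columns ([cell_density()] output).
#' @return data.frame with one row per patient (and selector/compartment
#'   combination): `patient_id`, `selector`, `compartment`, `n_roi`,
#'   `density`.
#' @export
patient_mean <- function(records) {
  key <- interaction(records$patient_id, records$selector,
                     records$compartment, drop = TRUE)
  out <- lapply(split(records, key), function(d)
    data.frame(patient_id = d$patient_id[1], selector = d$selector[1],
               compartment = d$compartment[1], n_roi = nrow(d),
               density = mean(d$density), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[order(out$patient_id, out$selector, out$compartment), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parenchymal to stromal density ratio
#'
#' The intratumoural CD8 distribution statistic: parenchymal density divided
#' by stromal density. A zero stromal density with positive parenchymal
#' density gives `Inf`; both zero gives `NaN` (undefined).
#'
#' @param dp parenchymal density, cells/mm2 (vectorised).
#' @param ds stromal density, cells/mm2.
#' @return numeric ratio vector.
#' @export
parenchyma_stroma_ratio <- function(dp, ds) {
  if (any(dp < 0, na.rm = TRUE) || any(ds < 0, na.rm = TRUE))
    stop_("densities must be nonnegative")
  ifelse(ds == 0, ifelse(dp > 0, Inf, NaN), dp / ds)
}

#' Flag ROIs with marginal compartment representation
#'
#' Sensitivity-check helper: flags tumour ROIs whose stroma or parenchyma
#' occupies less than `min_fraction` of the masked tissue area. Flagging
#' never drops data; downstream analyses decide what to do with the flag.
#'
#' @param masks a `region_mask` or list of them.
#' @param min_fraction minimum acceptable share of either compartment.
#' @return data.frame: `roi_id`, `parenchyma_fraction`, `stroma_fraction`,
#'   `flagged`.
#' @export
flag_marginal_rois <- function(masks, min_fraction = 0.05) {
  if (inherits(masks, "region_mask")) masks <- list(masks)
  out <- lapply(masks, function(m) {
    a <- compartment_areas(m)
    tot <- sum(a)
    pf <- if (tot > 0) unname(a["parenchyma"]) / tot else NA_real_
    sf <- if (tot > 0) unname(a["stroma"]) / tot else NA_real_
    data.frame(roi_id = m$roi_id, parenchyma_fraction = pf,
               stroma_fraction = sf,
               flagged = isTRUE(pf < min_fraction) | isTRUE(sf < min_fraction),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
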