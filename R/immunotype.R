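#' Classify one ROI into a spatial immunotype
#'
#' Three-class rule on CD8 T-cell densities: an ROI with overall CD8 density
#' strictly below the density cutoff (200 cells/mm2) is `depleted`;
#' otherwise the parenchymal:stromal density ratio decides between
#' `compartmentalised` (ratio below the cutoff) and `enriched` (ratio at or
#' above it). The primary classifier version uses a ratio cutoff of 0.5, the
#' revised version 0.6. Boundary convention: density exactly at 200 is not
#' depleted; ratio exactly at the cutoff is enriched (half-open intervals,
#' recorded in the output).
#'
#' A zero stromal density with positive parenchymal density gives an
#' infinite ratio, hence `enriched`. Both compartment densities zero while
#' the overall density is positive is geometrically impossible for a single
#' ROI; such input is flagged with a warning and labelled
#' `compartmentalised` (no demonstrable parenchymal infiltration) so the
#' classifier stays total.
#'
#' @param overall overall CD8 density over the whole ROI area, cells/mm2
#'   (vectorised).
#' @param dp parenchymal CD8 density, cells/mm2.
#' @param ds stromal CD8 density, cells/mm2.
#' @param version `"primary"` (ratio cutoff 0.5) or `"revised"` (0.6).
#' @param params an [analysis_params()] carrying the cutoffs.
#' @param id optional ROI identifier(s) recorded in the output.
#' @return data.frame (`immunotype_call`): `level`, `id`, `overall_cd8`,
#'   `parenchymal_cd8`, `stromal_cd8`, `ratio`, `label`,
#'   `classifier_version`, `aggregation`.
#' @export
classify_roi <- function(overall, dp, ds, version = c("primary", "revised"),
                         params = analysis_params(), id = NA_character_) {
  version <- match.arg(version)
  if (any(c(overall, dp, ds) < 0, na.rm = TRUE))
    stop_("densities must be nonnegative")
  n <- max(length(overall), length(dp), length(ds))
  overall <- rep_len(overall, n); dp <- rep_len(dp, n); ds <- rep_len(ds, n)
  id <- rep_len(id, n)
  rc <- unname(params$ratio_cutoff[version])
  ratio <- parenchyma_stroma_ratio(dp, ds)
  inconsistent <- dp == 0 & ds == 0 & overall > 0
  if (any(inconsistent))
    warning(sprintf("%d ROI(s) report positive overall CD8 density with zero density in both compartments; labelled compartmentalised",
                    sum(inconsistent)), call. = FALSE)
  label <- ifelse(overall < params$density_cutoff, "depleted",
                  ifelse(is.nan(ratio), "compartmentalised",
                         ifelse(ratio < rc, "compartmentalised", "enriched")))
  data.frame(level = "roi", id = id, overall_cd8 = overall,
             parenchymal_cd8 = dp, stromal_cd8 = ds, ratio = ratio,
             label = label, classifier_version = version,
             aggregation = "none", stringsAsFactors = FALSE)
}

#' Aggregate ROI immunotype calls to the patient level
#'
#' Two published aggregation rules. `consensus`: the most frequent
#' immunotype among the patient's ROIs; when several labels tie for most
#' frequent, the densities of the tied ROIs are averaged and the averaged
#' densities reclassified (a three-way 1-1-1 tie resolves by the same rule
#' over all ROIs). `highest`: the highest immunotype present in at least one
#' ROI under the hierarchy enriched > compartmentalised > depleted.
#'
#' @param calls ROI-level [classify_roi()] output with `patient_id` column
#'   (add it before calling, e.g. from `roi_meta`).
#' @param mode `"consensus"` or `"highest"`.
#' @param params passed to the tie-break reclassification.
#' @return data.frame, one row per patient: `level = "patient"`, `id`,
#'   mean densities, `ratio`, `label`, `classifier_version`, `aggregation`,
#'   `n_roi`.
#' @export
classify_patient <- function(calls, mode = c("consensus", "highest"),
                             params = analysis_params()) {
  mode <- match.arg(mode)
  if (is.null(calls$patient_id))
    stop_("calls must carry a patient_id column")
  if (length(unique(calls$classifier_version)) > 1)
    stop_("mixed classifier versions in patient aggregation")
  version <- calls$classifier_version[1]
  hier <- IMMUNOTYPE_LEVELS  # depleted < compartmentalised < enriched
  out <- lapply(split(calls, calls$patient_id), function(d) {
    if (mode == "highest") {
      label <- hier[max(match(d$label, hier))]
    } else {
      tab <- table(d$label)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1) {
        label <- top
      } else {
        tied <- d[d$label %in% top, , drop = FALSE]
        label <- classify_roi(mean(tied$overall_cd8),
                              mean(tied$parenchymal_cd8),
                              mean(tied$stromal_cd8),
                              version = version, params = params)$label
      }
    }
    data.frame(level = "patient", id = d$patient_id[1],
               overall_cd8 = mean(d$overall_cd8),
               parenchymal_cd8 = mean(d$parenchymal_cd8),
               stromal_cd8 = mean(d$stromal_cd8),
               ratio = parenchyma_stroma_ratio(mean(d$parenchymal_cd8),
                                               mean(d$stromal_cd8)),
               label = label, classifier_version = version,
               aggregation = mode, n_roi = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag intratumour immunotype heterogeneity
#'
#' A patient is heterogeneous when at least two of their ROIs carry distinct
#' immunotype labels. Patients with a single ROI are not assessable and are
#' flagged as such (heterogeneous = FALSE).
#'
#' @param calls ROI-level calls with `patient_id` and `label` columns.
#' @return data.frame: `patient_id`, `n_roi`, `heterogeneous`,
#'   `assessable`, `labels` (";"-joined multiset).
#' @export
heterogeneity_flag <- function(calls) {
  out <- lapply(split(calls, calls$patient_id), function(d)
    data.frame(patient_id = d$patient_id[1], n_roi = nrow(d),
               heterogeneous = nrow(d) >= 2 &&
                 length(unique(d$label)) >= 2,
               assessable = nrow(d) >= 2,
               labels = paste(sort(d$label), collapse = ";"),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' CD8-density immunotype calls straight from a cell table and masks
#'
#' Convenience wrapper: computes the overall, parenchymal, and stromal CD8
#' densities of every tumour ROI (overall over the whole raster area) and
#' classifies each ROI.
#'
#' @param table a `cell_table` with compartments assigned.
#' @param masks the ROI masks (for areas).
#' @param cd8_type name of the CD8 T-cell type in the vocabulary.
#' @param version classifier version.
#' @param params analysis parameters.
#' @return ROI-level calls with a `patient_id` column, ready for
#'   [classify_patient()].
#' @export
immunotype_rois <- function(table, masks, cd8_type = "CD8 T-cell",
                            version = "primary",
                            params = analysis_params()) {
  areas <- mask_areas(masks)
  d_all <- cell_density(table, cell_types = cd8_type, compartment = "all",
                        areas = areas)
  d_par <- cell_density(table, cell_types = cd8_type,
                        compartment = "parenchyma", areas = areas)
  d_str <- cell_density(table, cell_types = cd8_type,
                        compartment = "stroma", areas = areas)
  stopifnot(identical(d_all$roi_id, d_par$roi_id),
            identical(d_all$roi_id, d_str$roi_id))
  calls <- classify_roi(d_all$density, d_par$density, d_str$density,
                        version = version, params = params,
                        id = d_all$roi_id)
  calls$patient_id <- d_all$patient_id
  calls
}
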