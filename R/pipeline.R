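#' Run the full spatial analysis pipeline
#'
#' Orchestrates every stage on a simulated cohort: tissue simulation,
#' compartment assignment, compartment densities, spatial graphs and
#' immune-neighbourhood detection, interaction testing, immunotype
#' classification (ROI and patient level), and survival association.
#' Outputs are deterministic CSV/JSON files: identical config, inputs and
#' seed give byte-identical outputs. A single master seed is fanned out to
#' per-stage child seeds (see [derive_seeds()]) so stages are individually
#' reproducible.
#'
#' @param config path to a YAML file or a named list. Recognised keys:
#'   `seed` (integer), `out_dir` (required), `simulate` (list with
#'   `n_patients` named counts, `rois_per_patient`, `heterogeneity_rate`,
#'   `width`, `height`), `params` (overrides for [analysis_params()]
#'   fields), `classifier_version`, `aggregation`, `interaction_pairs`
#'   (list of 2-vectors), `horizon_months`. Unknown keys raise a schema
#'   error naming the key.
#' @return a `run_report` list (config snapshot, per-stage record counts,
#'   seeds, warnings, output manifest with md5 checksums), invisibly;
#'   also written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "simulate", "params", "classifier_version",
             "aggregation", "interaction_pairs", "horizon_months")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_("unknown config key '%s'", unknown[1])
  if (is.null(config$out_dir)) stop_("config must set out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  params <- do.call(analysis_params,
                    c(config$params %||% list(), list(rng_seed = seed)))
  version <- config$classifier_version %||% "primary"
  aggregation <- config$aggregation %||% "consensus"
  horizon <- config$horizon_months %||% 8
  seeds <- derive_seeds(seed, 4L)
  warnings <- character()
  counts <- list()

  # stage 1: simulate -------------------------------------------------
  sim <- config$simulate %||% list()
  np <- unlist(sim$n_patients %||% c(depleted = 4, compartmentalised = 4,
                                     enriched = 4))
  cohort <- generate_cohort(
    n_patients = np,
    rois_per_patient = sim$rois_per_patient %||% 2,
    heterogeneity_rate = sim$heterogeneity_rate %||% 1 / 3,
    width = sim$width %||% 600, height = sim$height %||% 600,
    seed = seeds[1])
  counts$cells <- n_cells(cohort$cells)
  counts$rois <- length(cohort$masks)
  counts$patients <- nrow(cohort$clinical)
  write_cell_table(cohort$cells, file.path(out_dir, "cells.csv"),
                   meta_path = file.path(out_dir, "roi_meta.csv"))
  write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
            row.names = FALSE)

  # stage 2: compartment densities -------------------------------------
  areas <- mask_areas(cohort$masks)
  dens <- rbind(
    cell_density(cohort$cells, "CD8 T-cell", compartment = "all",
                 areas = areas),
    cell_density(cohort$cells, "CD8 T-cell", compartment = "parenchyma",
                 areas = areas),
    cell_density(cohort$cells, "CD8 T-cell", compartment = "stroma",
                 areas = areas))
  write.csv(dens, file.path(out_dir, "densities.csv"), row.names = FALSE)
  counts$density_records <- nrow(dens)

  # stage 3: graphs, profiles, neighbourhoods --------------------------
  profiles <- do.call(rbind, lapply(cohort$cells$roi_meta$roi_id,
    function(rid) {
      g <- build_knn_graph(roi_cells(cohort$cells, rid), k = params$knn_k,
                           max_dist = params$knn_max_dist, roi_id = rid)
      neighbour_profile(g, cohort$cells)
    }))
  assignment <- detect_neighbourhoods(profiles,
                                      n_centres = params$n_centres,
                                      seed = seeds[2])
  assignment <- label_neighbourhood_semantics(assignment, cohort$cells)
  labels_df <- data.frame(
    roi_id = sub("\\|.*$", "", names(assignment$labels)),
    cell_id = sub("^[^|]*\\|", "", names(assignment$labels)),
    in_cluster = unname(assignment$labels),
    in_label = unname(assignment$semantic_names[
      as.character(assignment$labels)]),
    stringsAsFactors = FALSE)
  write.csv(labels_df, file.path(out_dir, "in_labels.csv"),
            row.names = FALSE)
  ind <- in_density(assignment, cohort$cells, areas = areas)
  write.csv(ind, file.path(out_dir, "in_density.csv"), row.names = FALSE)
  counts$immune_cells_clustered <- length(assignment$labels)

  # stage 4: interaction testing ---------------------------------------
  pairs <- config$interaction_pairs %||% list(c("CD8 T-cell", "APC"))
  pairs <- lapply(pairs, unlist)
  irec <- do.call(rbind, lapply(cohort$cells$roi_meta$roi_id,
    function(rid) {
      g <- build_expansion_graph(roi_cells(cohort$cells, rid),
                                 expansion = params$expansion_dist,
                                 radii = params$cell_radius, roi_id = rid)
      permutation_interaction_test(g, cohort$cells, pairs,
                                   n_perm = params$n_permutations,
                                   tail_fraction = params$tail_fraction,
                                   seed = seeds[3])
    }))
  write.csv(irec, file.path(out_dir, "interactions.csv"),
            row.names = FALSE)
  counts$interaction_records <- nrow(irec)

  # stage 5: immunotype classification ---------------------------------
  roi_calls <- immunotype_rois(cohort$cells, cohort$masks,
                               version = version, params = params)
  pat_calls <- classify_patient(roi_calls, mode = aggregation,
                                params = params)
  write.csv(roi_calls, file.path(out_dir, "immunotype_roi.csv"),
            row.names = FALSE)
  write.csv(pat_calls, file.path(out_dir, "immunotype_patient.csv"),
            row.names = FALSE)
  isum <- summarise_interactions(irec,
                                 setNames(roi_calls$label,
                                          roi_calls$id))
  write.csv(isum, file.path(out_dir, "interaction_summary.csv"),
            row.names = FALSE)
  counts$patient_calls <- nrow(pat_calls)

  # stage 6: survival association --------------------------------------
  surv <- merge(cohort$clinical, pat_calls[, c("id", "label")],
                by.x = "patient_id", by.y = "id")
  surv$group <- factor(surv$label, levels = IMMUNOTYPE_LEVELS)
  present <- table(surv$group) > 0
  outcome <- list()
  if (sum(present) >= 2 && sum(surv$event) > 0) {
    lr <- logrank_test(surv[, c("time", "event", "group")])
    outcome$logrank <- lr[c("statistic", "df", "p_value")]
    if (all(present))
      outcome$logrank_trend <- logrank_trend(
        surv[, c("time", "event", "group")])[c("statistic", "df",
                                               "p_value", "direction")]
  }
  outcome$median_pfs <- lapply(split(surv, surv$group, drop = TRUE),
                               function(d) km_curve(d)$median)
  jsonlite::write_json(outcome, file.path(out_dir, "outcome.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts$survival_patients <- nrow(surv)

  files <- c("cells.csv", "roi_meta.csv", "clinical.csv", "densities.csv",
             "in_labels.csv", "in_density.csv", "interactions.csv",
             "interaction_summary.csv", "immunotype_roi.csv",
             "immunotype_patient.csv", "outcome.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))),
                         stringsAsFactors = FALSE)
  report <- list(config = config, params = unclass(params),
                 seed = seed, stage_seeds = seeds, counts = counts,
                 warnings = warnings, manifest = manifest)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): %d patients, %d ROIs, %d cells\n",
              x$seed, x$counts$patients, x$counts$rois, x$counts$cells))
  cat("outputs:\n")
  print(x$manifest)
  invisible(x)
}
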