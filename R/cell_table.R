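#' Phenotyped single-cell table
#'
#' The central container of the pipeline: one row per segmented cell with its
#' ROI, patient, centroid coordinates in micrometres, phenotype, optional
#' subset flags (e.g. gated marker-positive populations), and a
#' microanatomical compartment label filled in by [assign_compartments()].
#'
#' @param cells data.frame with columns `cell_id`, `roi_id`, `patient_id`,
#'   `x`, `y`, `cell_type`; optional `subsets` (";"-separated flag strings)
#'   and `compartment`. Additional numeric columns (e.g. channel intensities)
#'   are carried through untouched.
#' @param roi_meta data.frame with one row per ROI: `roi_id`, `patient_id`,
#'   `roi_kind` (`"tumour"` or `"interface"`), `roi_area_um2` (may be `NA`
#'   when densities will be derived from mask areas), `pixel_size_um`.
#'   Derived from `cells` when `NULL`.
#' @param type_vocabulary ordered character vector of allowed cell types;
#'   inferred from the data when `NULL`.
#' @param immune_types subset of the vocabulary flagged as immune cells.
#' @return object of class `cell_table`.
#' @export
cell_table <- function(cells, roi_meta = NULL, type_vocabulary = NULL,
                       immune_types = character()) {
  req <- c("cell_id", "roi_id", "patient_id", "x", "y", "cell_type")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stop_("missing mandatory column '%s'", miss[1])
  cells$cell_id <- as.character(cells$cell_id)
  cells$roi_id <- as.character(cells$roi_id)
  cells$patient_id <- as.character(cells$patient_id)
  cells$cell_type <- as.character(cells$cell_type)
  if (is.null(cells$subsets)) cells$subsets <- rep("", nrow(cells))
  cells$subsets[is.na(cells$subsets)] <- ""
  if (is.null(cells$compartment))
    cells$compartment <- rep("unassigned", nrow(cells))
  if (nrow(cells)) {
    bad <- which(!is.finite(cells$x) | !is.finite(cells$y))
    if (length(bad))
      stop_("non-finite coordinate at row %d", bad[1])
    if (anyDuplicated(paste(cells$roi_id, cells$cell_id)))
      stop_("cell_id values must be unique within each ROI")
  }
  type_vocabulary <- type_vocabulary %||% sort(unique(cells$cell_type))
  unknown <- setdiff(unique(cells$cell_type), type_vocabulary)
  if (length(unknown))
    stop_("cell type(s) outside declared vocabulary: %s",
          paste(unknown, collapse = ", "))
  if (length(setdiff(immune_types, type_vocabulary)))
    stop_("immune_types must be a subset of the type vocabulary")
  if (is.null(roi_meta)) {
    u <- unique(cells[, c("roi_id", "patient_id")])
    roi_meta <- data.frame(roi_id = u$roi_id, patient_id = u$patient_id,
                           roi_kind = rep("tumour", nrow(u)),
                           roi_area_um2 = rep(NA_real_, nrow(u)),
                           pixel_size_um = rep(1, nrow(u)),
                           stringsAsFactors = FALSE)
  }
  roi_meta$roi_id <- as.character(roi_meta$roi_id)
  roi_meta$patient_id <- as.character(roi_meta$patient_id)
  if (nrow(cells) && length(setdiff(cells$roi_id, roi_meta$roi_id)))
    stop_("every cell's roi_id must appear in roi_meta")
  if (any(!is.na(roi_meta$roi_area_um2) & roi_meta$roi_area_um2 <= 0))
    stop_("roi_area_um2 must be positive")
  structure(list(cells = cells, roi_meta = roi_meta,
                 type_vocabulary = type_vocabulary,
                 immune_types = immune_types),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells, %d ROIs, %d patients, %d cell types (%d immune)\n",
              nrow(x$cells), nrow(x$roi_meta),
              length(unique(x$roi_meta$patient_id)),
              length(x$type_vocabulary), length(x$immune_types)))
  invisible(x)
}

#' Number of cells in a table
#' @param x a `cell_table`.
#' @param ... unused.
#' @export
n_cells <- function(x, ...) nrow(x$cells)

#' Extract one ROI's cells
#' @param table a `cell_table`.
#' @param roi_id ROI identifier.
#' @return data.frame of that ROI's cells.
#' @export
roi_cells <- function(table, roi_id) {
  if (!roi_id %in% table$roi_meta$roi_id)
    stop_("unknown roi_id '%s'", roi_id)
  table$cells[table$cells$roi_id == roi_id, , drop = FALSE]
}

#' Read a phenotyped cell table from delimited text
#'
#' @param path CSV/TSV file with a header row.
#' @param schema named list mapping the canonical field names (`cell_id`,
#'   `roi_id`, `patient_id`, `x`, `y`, `cell_type`, optionally `subsets`,
#'   `compartment`) to column names in the file. Defaults to identity.
#' @param roi_meta optional ROI metadata data.frame (see [cell_table()]), or
#'   path to a CSV holding it.
#' @param type_vocabulary,immune_types passed to [cell_table()].
#' @param sep field separator.
#' @return a `cell_table`; the row count of the file is preserved.
#' @export
read_cell_table <- function(path, schema = list(), roi_meta = NULL,
                            type_vocabulary = NULL,
                            immune_types = character(), sep = ",") {
  if (!file.exists(path)) stop_("file not found: %s", path)
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  canon <- c("cell_id", "roi_id", "patient_id", "x", "y", "cell_type",
             "subsets", "compartment")
  map <- setNames(as.list(canon), canon)
  map[names(schema)] <- schema
  mandatory <- c("cell_id", "roi_id", "patient_id", "x", "y", "cell_type")
  for (f in mandatory)
    if (!map[[f]] %in% names(raw))
      stop_("missing mandatory column '%s'", map[[f]])
  cells <- data.frame(cell_id = raw[[map$cell_id]],
                      roi_id = raw[[map$roi_id]],
                      patient_id = raw[[map$patient_id]],
                      x = raw[[map$x]], y = raw[[map$y]],
                      cell_type = raw[[map$cell_type]],
                      stringsAsFactors = FALSE)
  for (f in c("subsets", "compartment"))
    if (map[[f]] %in% names(raw)) cells[[f]] <- raw[[map[[f]]]]
  for (axis in c("x", "y")) {
    v <- cells[[axis]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "")
      if (length(bad))
        stop_("non-numeric %s coordinate at row %d", axis, bad[1])
      cells[[axis]] <- conv
    }
  }
  extra <- setdiff(names(raw), unlist(map))
  for (col in extra) cells[[col]] <- raw[[col]]
  if (is.character(roi_meta)) roi_meta <- read.csv(roi_meta,
                                                   stringsAsFactors = FALSE)
  cell_table(cells, roi_meta = roi_meta, type_vocabulary = type_vocabulary,
             immune_types = immune_types)
}

#' Write a cell table (and optionally its ROI metadata) to CSV
#'
#' Columns are written in a fixed canonical order so output is
#' byte-reproducible.
#'
#' @param table a `cell_table`.
#' @param path output CSV path for the cells.
#' @param meta_path optional output CSV path for `roi_meta`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, meta_path = NULL) {
  cells <- table$cells
  lead <- c("cell_id", "roi_id", "patient_id", "x", "y", "cell_type",
            "subsets", "compartment")
  ord <- c(lead, sort(setdiff(names(cells), lead)))
  cells <- cells[, ord, drop = FALSE]
  # 17 significant digits so doubles survive the text round trip bit-exactly
  for (col in names(cells))
    if (is.double(cells[[col]]))
      cells[[col]] <- sprintf("%.17g", cells[[col]])
  write.csv(cells, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path))
    write.csv(table$roi_meta, meta_path, row.names = FALSE)
  invisible(path)
}
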