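#' Compartment label mask
#'
#' A single-channel integer raster at (by default) 1 um2/pixel assigning each
#' pixel to a microanatomical compartment. Label 0 is background; every
#' nonzero label must be declared in `semantics`.
#'
#' Coordinate convention: origin at the raster top-left, x rightward along
#' columns, y downward along rows; pixel (i, j) (1-based row/column) covers
#' the half-open square `[(j-1), j) x [(i-1), i)` in micrometre units at
#' pixel size 1.
#'
#' @param labels integer matrix of pixel labels.
#' @param semantics named character vector mapping label values (as names) to
#'   compartment names, e.g. `c("1" = "parenchyma", "2" = "stroma")`.
#' @param pixel_size_um physical pixel edge length, um.
#' @param roi_id identifier of the ROI the mask belongs to.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(labels, semantics, pixel_size_um = 1,
                        roi_id = NA_character_) {
  if (!is.matrix(labels)) stop_("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (is.null(names(semantics)) || any(names(semantics) == ""))
    stop_("semantics must be a fully named vector (label -> compartment)")
  semantics <- setNames(as.character(semantics), names(semantics))
  present <- unique(as.vector(labels))
  unknown <- setdiff(present, c(0L, as.integer(names(semantics))))
  if (length(unknown))
    stop_("unknown mask label(s): %s", paste(sort(unknown), collapse = ", "))
  if (pixel_size_um <= 0) stop_("pixel_size_um must be positive")
  structure(list(labels = labels, semantics = semantics,
                 pixel_size_um = pixel_size_um, roi_id = roi_id),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s': %d x %d px at %g um/px; compartments: %s\n",
              x$roi_id, nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              paste(unique(x$semantics), collapse = ", ")))
  invisible(x)
}

#' Read a compartment mask from a single-channel 16-bit TIFF
#'
#' @param path TIFF file path.
#' @param semantics label-to-compartment mapping (see [region_mask()]).
#' @param pixel_size_um physical pixel size, um.
#' @param roi_id ROI identifier.
#' @return a `region_mask` with labels preserved bit-exactly.
#' @export
read_region_mask <- function(path, semantics, pixel_size_um = 1,
                             roi_id = NA_character_) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2)
    stop_("expected a single-channel image, got %d channels", dim(img)[3])
  labels <- matrix(as.integer(img), nrow = dim(img)[1])
  region_mask(labels, semantics, pixel_size_um = pixel_size_um,
              roi_id = roi_id)
}

#' Write a compartment mask as a single-channel 16-bit TIFF
#'
#' @param mask a `region_mask` with labels in `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path) {
  lb <- mask$labels
  if (any(lb < 0L | lb > 65535L))
    stop_("labels must fit a 16-bit image (0..65535)")
  tiff::writeTIFF(lb / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}
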