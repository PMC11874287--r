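#' Arcsinh intensity transform
#'
#' Elementwise `asinh(x / cofactor)`, the standard variance-stabilising
#' transform for mass-cytometry channel intensities. Strictly monotone and
#' order preserving.
#'
#' @param values numeric vector or array of nonnegative intensities.
#' @param cofactor positive scaling cofactor (default 0.5).
#' @return transformed values, same shape as the input.
#' @export
arcsinh_transform <- function(values, cofactor = 0.5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || !is.finite(cofactor) ||
      cofactor <= 0)
    stop_("cofactor must be a single positive number")
  asinh(values / cofactor)
}

#' Percentile normalisation of a channel
#'
#' Normalises channel intensities to `[0, 1]`: values are clipped to the
#' `[p_low, p_high]` percentile range, affinely rescaled, and rescaled values
#' below `floor` are set to 0 (background removal). A degenerate percentile
#' range (constant input, or `p_low` and `p_high` hitting the same value)
#' yields an all-zero output rather than an error.
#'
#' Optimal percentiles and floors are channel specific and must be chosen by
#' the analyst; defaults are `p_low = 0`, `p_high = 99`, `floor = 0`.
#'
#' @param channel numeric vector or matrix (raster) of intensities.
#' @param p_low,p_high percentiles in `[0, 100]`, `p_low < p_high`.
#' @param floor rescaled values strictly below this threshold are zeroed.
#' @return same shape as `channel`, values in `[0, 1]`.
#' @export
percentile_normalise <- function(channel, p_low = 0, p_high = 99, floor = 0) {
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop_("percentiles must satisfy 0 <= p_low < p_high <= 100")
  lo <- quantile(channel, p_low / 100, na.rm = TRUE, names = FALSE)
  hi <- quantile(channel, p_high / 100, na.rm = TRUE, names = FALSE)
  out <- channel
  if (hi <= lo) {
    out[] <- 0
    return(out)
  }
  out[] <- (pmin(pmax(channel, lo), hi) - lo) / (hi - lo)
  out[out < floor] <- 0
  out
}
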