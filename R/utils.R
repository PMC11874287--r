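`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

#' Draw reproducible child seeds from one master seed
#'
#' Stages of the pipeline (and replicate loops in simulations) consume their
#' own seeds so that any stage can be rerun in isolation. Child seeds are the
#' first `n` draws of `sample.int(.Machine$integer.max - 1L)` after seeding
#' the generator with `seed`, which keeps them within 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Pairwise Euclidean distances between rows of (x1,y1) and all (x2,y2),
# computed chunk-wise so memory stays bounded for large ROIs.
dist_rows <- function(x1, y1, x2, y2) {
  dx <- outer(x1, x2, "-")
  dy <- outer(y1, y2, "-")
  sqrt(dx * dx + dy * dy)
}

# Split flag strings ("PD1+;TRM") into character vectors.
split_subsets <- function(s) {
  s[is.na(s)] <- ""
  strsplit(s, ";", fixed = TRUE)
}

has_flag <- function(subsets, flag) {
  vapply(split_subsets(subsets), function(f) flag %in% f, logical(1))
}
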