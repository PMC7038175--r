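## Internal helpers shared across modules.
##
## Coordinate convention, used everywhere in the package: arrays are indexed
## (x, y, z) = (axis 1, axis 2, axis 3), x fastest in memory (R column-major
## order). Flow component u displaces along axis 1, v along axis 2, w along
## axis 3, all in voxel units.

as_volume <- function(x) {
  if (is.null(dim(x))) stop("volume must be a matrix or array", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

vol_ndim <- function(x) length(dim(x))

## Correlation with a centred 1D kernel along `axis` (reflected boundaries).
correlate_axis <- function(x, kernel, axis) {
  d <- dim(x)
  out <- cpp_correlate1d(as.numeric(x), as.integer(d), as.numeric(kernel),
                         as.integer(axis - 1L))
  array(out, d)
}

## Separable correlation: one 1D kernel per axis (list of length ndim).
correlate_separable <- function(x, kernels) {
  for (a in seq_along(kernels)) x <- correlate_axis(x, kernels[[a]], a)
  x
}

## Name of a coefficient index, e.g. c(1, 0, 0) -> "100".
idx_name <- function(idx) paste0(idx, collapse = "")

## All index tuples (one per row) with total order <= order_max in `ndim`
## dimensions, ordered by total order then lexicographically.
index_table <- function(order_max, ndim) {
  grid <- as.matrix(expand.grid(rep(list(0:order_max), ndim)))
  colnames(grid) <- NULL
  grid <- grid[rowSums(grid) <= order_max, , drop = FALSE]
  ord <- rowSums(grid)
  keys <- c(list(ord), lapply(seq_len(ndim), function(a) grid[, a]))
  grid <- grid[do.call(order, keys), , drop = FALSE]
  storage.mode(grid) <- "integer"
  grid
}

## Normalized Gaussian window values on the integer support.
window_weights <- function(sigma, radius) {
  x <- (-radius):radius
  w <- exp(-(x / sigma)^2)
  w / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
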