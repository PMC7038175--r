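## The discrete Hermite transform: Gaussian-windowed local decomposition of a
## 1D/2D/3D signal onto polynomials orthonormal under the squared Gaussian
## window, computed as separable correlations with Gaussian-derivative-like
## kernels, plus the inverse (synthesis) reconstruction.

#' Generalized Hermite polynomial
#'
#' Evaluates the physicists' Hermite polynomial \eqn{H_l(x/\sigma)} given by
#' Rodrigues' formula, using the stable three-term recurrence
#' \eqn{H_{l+1}(t) = 2 t H_l(t) - 2 l H_{l-1}(t)}.
#'
#' @param l Non-negative integer order.
#' @param x Numeric scalar, vector or array of evaluation points.
#' @param sigma Positive scale; the polynomial is evaluated at `x / sigma`.
#' @return Numeric object of the same shape as `x`.
#' @examples
#' hermite_polynomial(2, c(-1, 0, 1), 1) # 4 t^2 - 2
#' @export
hermite_polynomial <- function(l, x, sigma = 1) {
  if (length(l) != 1 || l < 0 || l != round(l)) {
    stop("'l' must be a single non-negative integer", call. = FALSE)
  }
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  t <- x / sigma
  h_prev <- rep(1, length(t))
  if (l == 0) return(array_like(h_prev, x))
  h <- 2 * t
  if (l == 1) return(array_like(h, x))
  for (k in 1:(l - 1)) {
    h_next <- 2 * t * h - 2 * k * h_prev
    h_prev <- h
    h <- h_next
  }
  array_like(h, x)
}

array_like <- function(values, template) {
  if (!is.null(dim(template))) dim(values) <- dim(template)
  values
}

## 1D polynomials orthonormal under the *discrete* squared Gaussian weight
## on the integer support. They converge to the normalized Hermite
## polynomials as the window grows; orthonormalizing against the sampled
## weight (rather than sampling the continuous polynomials) is what makes
## the analysis/synthesis pair reproduce polynomials exactly.
discrete_hermite_basis <- function(order_max, sigma, radius) {
  x <- (-radius):radius
  w <- window_weights(sigma, radius)
  Q <- matrix(0, length(x), order_max + 1)
  ## monomial coefficients of each basis polynomial (row d+1 = x^d term)
  C <- matrix(0, order_max + 2, order_max + 1)
  for (l in 0:order_max) {
    v <- x^l
    cf <- numeric(order_max + 2)
    cf[l + 1] <- 1
    for (pass in 1:2) { # twice for numerical stability (modified Gram-Schmidt)
      for (j in seq_len(l)) {
        proj <- sum(w * v * Q[, j])
        v <- v - proj * Q[, j]
        cf <- cf - proj * C[, j]
      }
    }
    nrm <- sqrt(sum(w * v^2))
    if (!is.finite(nrm) || nrm < 1e-10) {
      stop("degenerate polynomial basis: order too high for this window",
           call. = FALSE)
    }
    Q[, l + 1] <- v / nrm
    C[, l + 1] <- cf / nrm
  }
  list(x = x, w = w, Q = Q, C = C)
}

## Expansion coefficients of the position-derivative of a coefficient field:
## d/dx0 L_l(x0) = sum_j beta[l][j+1] * L_j(x0), exactly, for the field
## defined by discrete correlation with the (continuously extended) kernels.
## The derivative kernel is -t_l'(u) = w(u) * [(2u/sigma^2) Q_l(u) - Q_l'(u)],
## a degree-(l+1) polynomial under the window, expanded in the discrete
## orthonormal basis (exact for l + 1 <= order_max).
derivative_expansion <- function(basis, order_max, sigma) {
  polyval <- function(cf, x) {
    acc <- 0
    for (d in rev(seq_along(cf))) acc <- acc * x + cf[d]
    acc
  }
  lapply(0:max(order_max - 1, 0), function(l) {
    cf <- basis$C[, l + 1]
    ## (2/sigma^2) * u * Q_l(u): shift coefficients up one degree
    cf_up <- c(0, cf[-length(cf)]) * (2 / sigma^2)
    ## Q_l'(u)
    cf_d <- c(cf[-1] * seq_len(length(cf) - 1), 0)
    p <- polyval(cf_up - cf_d, basis$x)
    vapply(0:(l + 1), function(j) sum(basis$w * p * basis$Q[, j + 1]), 0)
  })
}

#' Hermite analysis filter bank
#'
#' Builds the separable analysis filter bank of the N-dimensional Hermite
#' transform: one 1D Gaussian-derivative-like kernel per axis order, combined
#' as outer products over all index tuples of total order up to `order_max`.
#' Kernels are normalized so the order-0 kernel has unit DC gain, making the
#' order-0 coefficient an intensity-preserving local average.
#'
#' @param order_max Maximum total expansion order `N` (>= 0).
#' @param window_size Odd kernel support `M` per axis. Must satisfy
#'   `order_max <= 2 * (window_size - 1)`; in addition `order_max <=
#'   window_size - 1` is required because only `window_size` linearly
#'   independent polynomials exist on the discrete support.
#' @param sigma Gaussian window scale in voxels. Defaults to a quarter of the
#'   window, so +/- 2 sigma spans the kernel.
#' @param ndim Dimensionality of the signals to analyze (1, 2 or 3).
#' @return An object of class `hermite_bank`.
#' @examples
#' bank <- hermite_filter_bank(order_max = 4, window_size = 5, ndim = 3)
#' nrow(bank$indices) # 35 filters
#' @export
hermite_filter_bank <- function(order_max, window_size = 5,
                                sigma = (window_size - 1) / 4, ndim = 3) {
  if (order_max < 0 || order_max != round(order_max)) {
    stop("'order_max' must be a non-negative integer", call. = FALSE)
  }
  if (window_size < 1 || window_size %% 2 != 1) {
    stop("'window_size' must be a positive odd integer", call. = FALSE)
  }
  if (order_max > 2 * (window_size - 1)) {
    stop("invalid configuration: order_max must satisfy N <= 2*(M-1)",
         call. = FALSE)
  }
  if (order_max > window_size - 1) {
    stop("invalid configuration: order_max must be <= window_size - 1 ",
         "(only window_size independent polynomials exist on the support)",
         call. = FALSE)
  }
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (!ndim %in% 1:3) stop("'ndim' must be 1, 2 or 3", call. = FALSE)
  radius <- (window_size - 1) %/% 2
  basis <- discrete_hermite_basis(order_max, sigma, radius)
  ## Correlation-form kernels t_l(u) = w(u) Q_l(u); the convolution-form
  ## analysis filter is D_l(u) = (-1)^l t_l(u) (reflected arguments).
  corr_kernels <- lapply(0:order_max, function(l) basis$w * basis$Q[, l + 1])
  indices <- index_table(order_max, ndim)
  structure(list(
    order_max = as.integer(order_max),
    window_size = as.integer(window_size),
    radius = as.integer(radius),
    sigma = sigma,
    ndim = as.integer(ndim),
    indices = indices,
    kernels1d = corr_kernels,
    polynomials = basis$Q,
    window = basis$w,
    deriv_coeffs = derivative_expansion(basis, order_max, sigma)
  ), class = "hermite_bank")
}

#' @export
print.hermite_bank <- function(x, ...) {
  cat(sprintf("Hermite filter bank: N = %d, window %d^%d, sigma = %.3g (%d filters)\n",
              x$order_max, x$window_size, x$ndim, x$sigma, nrow(x$indices)))
  invisible(x)
}

#' Full N-dimensional analysis filter
#'
#' Outer product of the bank's 1D kernels for one index tuple, in
#' convolution form (including the reflected-argument sign). Mainly useful
#' for inspecting the bank and for validating the separable path against a
#' direct convolution.
#'
#' @param bank A [hermite_filter_bank()] object.
#' @param index Integer vector of per-axis orders (length `ndim`).
#' @return A numeric array of size `window_size^ndim`.
#' @export
hermite_filter <- function(bank, index) {
  stopifnot(inherits(bank, "hermite_bank"), length(index) == bank$ndim)
  k <- lapply(seq_len(bank$ndim), function(a) {
    (-1)^index[a] * bank$kernels1d[[index[a] + 1]]
  })
  out <- k[[1]]
  if (bank$ndim >= 2) out <- outer(out, k[[2]])
  if (bank$ndim == 3) out <- outer(out, k[[3]])
  out
}

## Correlation-form outer-product kernel for one index (internal; the
## exported hermite_filter() returns the convolution form).
correlation_kernel <- function(bank, index) {
  k <- lapply(seq_len(bank$ndim), function(a) bank$kernels1d[[index[a] + 1]])
  out <- k[[1]]
  if (bank$ndim >= 2) out <- outer(out, k[[2]])
  if (bank$ndim == 3) out <- outer(out, k[[3]])
  out
}

#' Forward Hermite transform
#'
#' Decomposes a volume into Cartesian Hermite coefficients: each coefficient
#' grid is the correlation of the signal with the corresponding separable
#' analysis kernel, optionally subsampled on a regular lattice.
#'
#' @param volume Numeric matrix (2D) or array (3D).
#' @param bank A [hermite_filter_bank()] whose `ndim` matches the volume.
#' @param stride Positive integer subsampling step of the coefficient
#'   lattice (1 = dense transform, the default used for optical flow).
#' @return An object of class `hermite_coeffs`: a list of coefficient grids
#'   named by their index tuple (e.g. `"100"`), plus transform metadata.
#' @examples
#' bank <- hermite_filter_bank(2, 5, ndim = 2)
#' co <- hermite_transform(matrix(rnorm(64), 8, 8), bank)
#' names(co$coeffs)
#' @export
hermite_transform <- function(volume, bank, stride = 1L) {
  volume <- as_volume(volume)
  nd <- vol_ndim(volume)
  if (nd != bank$ndim) {
    stop("volume dimensionality does not match the filter bank", call. = FALSE)
  }
  if (stride < 1 || stride != round(stride)) {
    stop("'stride' must be a positive integer", call. = FALSE)
  }
  if (any(stride > dim(volume))) {
    stop("'stride' larger than a volume dimension", call. = FALSE)
  }
  d <- dim(volume)
  ## Cache of partial separable passes, keyed by the orders applied so far.
  coeffs <- vector("list", nrow(bank$indices))
  names(coeffs) <- apply(bank$indices, 1, idx_name)
  partial <- list(root = volume)
  for (r in seq_len(nrow(bank$indices))) {
    idx <- bank$indices[r, ]
    key <- "root"
    for (a in seq_len(nd)) {
      new_key <- paste0(key, ".", idx[a])
      if (is.null(partial[[new_key]])) {
        partial[[new_key]] <- correlate_axis(partial[[key]],
                                             bank$kernels1d[[idx[a] + 1]], a)
      }
      key <- new_key
    }
    out <- partial[[key]]
    if (stride > 1) {
      sub <- lapply(d, function(n) seq(1, n, by = stride))
      out <- do.call(`[`, c(list(out), sub, list(drop = FALSE)))
    }
    coeffs[[r]] <- out
  }
  structure(list(
    coeffs = coeffs,
    indices = bank$indices,
    order_max = bank$order_max,
    sigma = bank$sigma,
    window_size = bank$window_size,
    stride = as.integer(stride),
    source_shape = d,
    ndim = bank$ndim,
    deriv_coeffs = bank$deriv_coeffs
  ), class = "hermite_coeffs")
}

#' @export
print.hermite_coeffs <- function(x, ...) {
  cat(sprintf("Hermite coefficients: N = %d, %d grids of %s (stride %d, source %s)\n",
              x$order_max, length(x$coeffs),
              paste(dim(x$coeffs[[1]]), collapse = "x"), x$stride,
              paste(x$source_shape, collapse = "x")))
  invisible(x)
}

## Rebuild the bank a coefficient set was produced with.
bank_of <- function(coeffs) {
  hermite_filter_bank(coeffs$order_max, coeffs$window_size,
                      sigma = coeffs$sigma, ndim = coeffs$ndim)
}

#' Inverse Hermite transform
#'
#' Reconstructs the analyzed signal from its Hermite coefficients by
#' interpolating them with the synthesis filters (the window-weighted
#' polynomials, normalized by the summed window energy over the sampling
#' lattice). For a dense transform (`stride = 1`) the reconstruction of any
#' polynomial signal of total degree `<= order_max` is exact away from the
#' boundary margin.
#'
#' @param coeffs A `hermite_coeffs` object from [hermite_transform()].
#' @return The reconstructed volume (numeric array of the source shape).
#' @export
hermite_reconstruct <- function(coeffs) {
  if (!inherits(coeffs, "hermite_coeffs")) {
    stop("'coeffs' must be a hermite_coeffs object", call. = FALSE)
  }
  if (is.null(coeffs$coeffs) || !length(coeffs$coeffs)) {
    stop("coefficient set is empty", call. = FALSE)
  }
  bank <- bank_of(coeffs)
  d <- coeffs$source_shape
  nd <- coeffs$ndim
  stride <- coeffs$stride
  acc <- array(0, d)
  for (r in seq_len(nrow(coeffs$indices))) {
    idx <- coeffs$indices[r, ]
    nm <- idx_name(idx)
    g <- coeffs$coeffs[[nm]]
    if (is.null(g)) stop("missing coefficient grid ", nm, call. = FALSE)
    if (stride > 1) {
      up <- array(0, d)
      sub <- lapply(d, function(n) seq(1, n, by = stride))
      up <- do.call(`[<-`, c(list(up), sub, list(value = g)))
      g <- up
    }
    ## Synthesis by correlation with the reflected kernel (-1)^l t_l per axis.
    kern <- lapply(seq_len(nd), function(a) {
      (-1)^idx[a] * bank$kernels1d[[idx[a] + 1]]
    })
    acc <- acc + correlate_separable(g, kern)
  }
  if (stride > 1) {
    ind <- array(0, d)
    sub <- lapply(d, function(n) seq(1, n, by = stride))
    ind <- do.call(`[<-`, c(list(ind), sub, list(value = 1)))
    wsum <- correlate_separable(ind, rep(list(bank$window), nd))
    wsum[wsum < 1e-12] <- 1e-12
    acc <- acc / wsum
  }
  acc
}

#' Spatial derivative of a coefficient field
#'
#' Computes the derivative of one Hermite coefficient grid with respect to
#' window position along one axis via the order-raising property: the
#' derivative kernel expands exactly in the next-higher (and lower) order
#' analysis kernels of the same axis, so the derivative is a short linear
#' combination of the neighbouring-order coefficient grids. (In the
#' continuous limit this is the classical identity
#' `d/dx L_l = sqrt(2 (l + 1)) / sigma * L_(l+1)`.)
#'
#' @param coeffs A `hermite_coeffs` object (dense transform, stride 1).
#' @param index Integer per-axis orders of the coefficient to differentiate.
#' @param axis Axis (1-based) along which to differentiate. The raised
#'   index along that axis must still exist in the set
#'   (`sum(index) < order_max`).
#' @return The derivative grid.
#' @export
coefficient_derivative <- function(coeffs, index, axis) {
  l <- index[axis]
  if (sum(index) + 1 > coeffs$order_max) {
    stop("cannot differentiate: raised index exceeds order_max", call. = FALSE)
  }
  beta <- coeffs$deriv_coeffs[[l + 1]]
  acc <- 0
  for (j in seq_along(beta) - 1) {
    if (abs(beta[j + 1]) < 1e-14) next
    idx <- index
    idx[axis] <- j
    acc <- acc + beta[j + 1] * coeffs$coeffs[[idx_name(idx)]]
  }
  acc
}
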