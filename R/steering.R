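## Orientation estimation and coefficient steering. The Cartesian Hermite
## coefficients of each total order n form a vector that rotates, under a
## change of local frame, by the orthonormal symmetric-power representation
## of the 3D (or 2D) rotation carrying the first steered axis onto the local
## orientation of maximum energy. Steering therefore conserves per-order
## energy and, at the first order, concentrates the gradient magnitude onto
## the on-axis coefficient.

#' Cartesian angular function
#'
#' Directional-selectivity weight of a steered filter:
#' `sqrt(choose(k, j)) * cos(angle)^j * sin(angle)^(k-j)`.
#'
#' @param j,k Integers with `0 <= j <= k`.
#' @param angle Angle(s) in radians (scalar, vector or array).
#' @return Numeric object shaped like `angle`. For fixed `k` the squares sum
#'   to one over `j = 0..k` at every angle.
#' @export
angular_function <- function(j, k, angle) {
  if (j < 0 || k < 0 || j > k) {
    stop("'j' and 'k' must satisfy 0 <= j <= k", call. = FALSE)
  }
  sqrt(choose(k, j)) * cos(angle)^j * sin(angle)^(k - j)
}

#' Local orientation of maximum energy
#'
#' Estimates per-voxel orientation angles from the first-order Hermite
#' coefficients, which approximate the (Gaussian-smoothed) spatial gradient.
#' `theta` is the in-plane angle `atan2(L010, L100)` and, in 3D, `phi` the
#' elevation from the z-axis, `atan2(sqrt(L100^2 + L010^2), L001)`. Both use
#' the quadrant-aware arctangent; voxels with zero gradient get angle 0 by
#' convention and can be recognized through the returned `energy` grid.
#'
#' @param coeffs A `hermite_coeffs` object containing the first-order grids.
#' @return An object of class `orientation_field` with grids `theta`, `phi`
#'   (`NULL` in 2D) and `energy` (gradient magnitude).
#' @export
estimate_orientation <- function(coeffs) {
  if (!inherits(coeffs, "hermite_coeffs")) {
    stop("'coeffs' must be a hermite_coeffs object", call. = FALSE)
  }
  nd <- coeffs$ndim
  gx <- coeffs$coeffs[[if (nd == 3) "100" else "10"]]
  gy <- coeffs$coeffs[[if (nd == 3) "010" else "01"]]
  if (is.null(gx) || is.null(gy)) {
    stop("first-order coefficients are missing", call. = FALSE)
  }
  theta <- atan2(gy, gx)
  if (nd == 3) {
    gz <- coeffs$coeffs[["001"]]
    if (is.null(gz)) stop("first-order coefficients are missing", call. = FALSE)
    rho <- sqrt(gx^2 + gy^2)
    phi <- atan2(rho, gz)
    energy <- sqrt(rho^2 + gz^2)
  } else {
    phi <- NULL
    energy <- sqrt(gx^2 + gy^2)
  }
  structure(list(theta = theta, phi = phi, energy = energy, ndim = nd),
            class = "orientation_field")
}

## Orthonormal local frame from the orientation angles. e1 points along the
## orientation; at the reference angles (theta, phi) = (0, pi/2) (3D) or
## theta = 0 (2D) the frame is the Cartesian frame, so steering there is the
## identity on all orders.
orientation_frame <- function(orientation) {
  th <- orientation$theta
  if (orientation$ndim == 3) {
    ph <- orientation$phi
    st <- sin(th); ct <- cos(th); sp <- sin(ph); cp <- cos(ph)
    list(
      e1 = list(sp * ct, sp * st, cp),
      e2 = list(-st, ct, array(0, dim(th)) + 0 * th),
      e3 = list(-cp * ct, -cp * st, sp)
    )
  } else {
    st <- sin(th); ct <- cos(th)
    list(e1 = list(ct, st), e2 = list(-st, ct))
  }
}

## Multinomial coefficient n! / prod(idx!)
multinom <- function(idx) {
  n <- sum(idx)
  exp(lgamma(n + 1) - sum(lgamma(idx + 1)))
}

## Steered coefficient for one steered index tuple P (p+q(+r) = n): expands
## the product (e1.u)^p (e2.u)^q (e3.u)^r as a homogeneous polynomial with
## per-voxel grid coefficients and contracts it against the Cartesian
## coefficients of order n with the Bombieri normalization weights.
steer_one <- function(order_coeffs, order_indices, frame, P) {
  nd <- length(P)
  ## polynomial as named list: key = monomial exponents, value = grid
  poly <- list()
  poly[[idx_name(rep(0L, nd))]] <- 1
  for (f in seq_len(nd)) {
    e <- frame[[f]]
    for (rep_i in seq_len(P[f])) {
      new_poly <- list()
      for (key in names(poly)) {
        expnt <- as.integer(strsplit(key, "")[[1]])
        g <- poly[[key]]
        for (comp in seq_len(nd)) {
          e2 <- expnt
          e2[comp] <- e2[comp] + 1L
          k2 <- idx_name(e2)
          term <- g * e[[comp]]
          new_poly[[k2]] <- if (is.null(new_poly[[k2]])) term else new_poly[[k2]] + term
        }
      }
      poly <- new_poly
    }
  }
  wP <- sqrt(multinom(P))
  out <- 0
  for (r in seq_len(nrow(order_indices))) {
    A <- order_indices[r, ]
    cA <- poly[[idx_name(A)]]
    if (is.null(cA)) next
    out <- out + (wP / sqrt(multinom(A))) * cA * order_coeffs[[r]]
  }
  out
}

#' Steer Hermite coefficients onto the local orientation
#'
#' Projects the Cartesian Hermite coefficients of every total order onto the
#' steered basis adapted to the per-voxel orientation: an orthonormal,
#' order-preserving change of basis. Steered index `(n, 0, 0)` is the
#' "on-axis" coefficient describing the 1D profile along the orientation.
#'
#' @param coeffs A `hermite_coeffs` object.
#' @param orientation An [estimate_orientation()] result on the same grids.
#' @return An object of class `steered_coeffs` with the same index layout as
#'   `coeffs` (steered-frame indices).
#' @export
steer_coefficients <- function(coeffs, orientation) {
  if (!inherits(coeffs, "hermite_coeffs")) {
    stop("'coeffs' must be a hermite_coeffs object", call. = FALSE)
  }
  if (!identical(dim(orientation$theta), dim(coeffs$coeffs[[1]]))) {
    stop("orientation grids do not match coefficient grids", call. = FALSE)
  }
  frame <- orientation_frame(orientation)
  nd <- coeffs$ndim
  out <- vector("list", nrow(coeffs$indices))
  names(out) <- apply(coeffs$indices, 1, idx_name)
  for (n in 0:coeffs$order_max) {
    sel <- rowSums(coeffs$indices) == n
    idxs <- coeffs$indices[sel, , drop = FALSE]
    if (n == 0) {
      out[[idx_name(rep(0L, nd))]] <- coeffs$coeffs[[idx_name(rep(0L, nd))]]
      next
    }
    grids <- coeffs$coeffs[apply(idxs, 1, idx_name)]
    for (r in seq_len(nrow(idxs))) {
      P <- idxs[r, ]
      out[[idx_name(P)]] <- steer_one(grids, idxs, frame, P)
    }
  }
  structure(list(
    coeffs = out,
    indices = coeffs$indices,
    order_max = coeffs$order_max,
    sigma = coeffs$sigma,
    ndim = nd,
    orientation = orientation
  ), class = "steered_coeffs")
}

#' @export
print.steered_coeffs <- function(x, ...) {
  cat(sprintf("Steered Hermite coefficients: N = %d, %d grids (%dD)\n",
              x$order_max, length(x$coeffs), x$ndim))
  invisible(x)
}

## Selected steered coefficients (list of index tuples) for one total order
## block; used by the flow module, which only needs the on-axis coefficient
## and its raised-order companions.
steer_rows <- function(coeffs, frame, rows) {
  n <- sum(rows[[1]])
  sel <- rowSums(coeffs$indices) == n
  idxs <- coeffs$indices[sel, , drop = FALSE]
  grids <- coeffs$coeffs[apply(idxs, 1, idx_name)]
  lapply(rows, function(P) steer_one(grids, idxs, frame, as.integer(P)))
}
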