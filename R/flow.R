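## The Hermite optical-flow estimator (HOF2D / HOF3D): a coarse-to-fine,
## warping-based minimization of a Horn-Schunck-family energy in which the
## brightness-constancy term acts on the order-0 Hermite coefficient and is
## augmented by constancy constraints on the on-axis steered Hermite
## coefficients of higher orders. Setting gamma = 0 drops the steered
## constraints, leaving a multiresolution Horn-Schunck baseline on the
## smoothed intensity channel.

#' Optical-flow parameters
#'
#' Bundles the tunable parameters of the estimator. Defaults are the tuned
#' regime for cardiac CT volumes: smoothness weight `alpha = 10`, steered
#' constraint weight `gamma = 100`, expansion order `N = 4` over a 5-voxel
#' window, 5 pyramid levels and at least 50 solver iterations per warp.
#'
#' @param alpha Positive smoothness weight.
#' @param gamma Non-negative weight of the steered-coefficient constraints;
#'   `0` gives the plain Horn-Schunck baseline mode.
#' @param order_max Maximum Hermite expansion order `N`.
#' @param window_size Odd Hermite window size per axis.
#' @param sigma Gaussian window scale (defaults to `(window_size - 1) / 4`).
#' @param levels Pyramid depth (clipped so the coarsest level keeps at least
#'   8 samples per axis).
#' @param iterations Maximum inner solver iterations per warp.
#' @param warps_per_level Outer warp/re-linearization passes per level.
#' @param solver_tolerance Convergence threshold on the mean absolute change
#'   of the flow increments.
#' @param baseline_mode If `TRUE`, force `gamma = 0` (pure multiresolution
#'   Horn-Schunck on the order-0 channel).
#' @param normalize_gamma If `TRUE` (default) `gamma` is divided by the
#'   number of active steered constraints, so its scale does not depend on
#'   `order_max`.
#' @param steered_levels Number of finest pyramid levels on which the
#'   steered constraints are active (default 1): decimation pushes texture
#'   toward the grid's resolution limit, where high-order coefficients are
#'   no longer reliable, so coarse levels use the intensity term alone.
#' @param max_increment Per-warp clamp on each flow-increment component in
#'   voxels (the linearization is only valid for sub-voxel updates).
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(alpha = 10, gamma = 100, order_max = 4,
                        window_size = 5, sigma = (window_size - 1) / 4,
                        levels = 5, iterations = 50, warps_per_level = 3,
                        solver_tolerance = 1e-4, baseline_mode = FALSE,
                        normalize_gamma = TRUE, steered_levels = 1L,
                        max_increment = 1) {
  if (alpha <= 0) stop("'alpha' must be positive", call. = FALSE)
  if (gamma < 0) stop("'gamma' must be non-negative", call. = FALSE)
  if (levels < 1) stop("'levels' must be >= 1", call. = FALSE)
  if (iterations < 1) stop("'iterations' must be >= 1", call. = FALSE)
  if (baseline_mode) gamma <- 0
  structure(list(alpha = alpha, gamma = gamma, order_max = as.integer(order_max),
                 window_size = as.integer(window_size), sigma = sigma,
                 levels = as.integer(levels), iterations = as.integer(iterations),
                 warps_per_level = as.integer(warps_per_level),
                 solver_tolerance = solver_tolerance,
                 baseline_mode = isTRUE(baseline_mode),
                 normalize_gamma = isTRUE(normalize_gamma),
                 steered_levels = as.integer(steered_levels),
                 max_increment = max_increment),
            class = "flow_params")
}

#' @export
print.flow_params <- function(x, ...) {
  cat(sprintf("flow_params: alpha=%g gamma=%g N=%d window=%d levels=%d iters=%d warps=%d%s\n",
              x$alpha, x$gamma, x$order_max, x$window_size, x$levels,
              x$iterations, x$warps_per_level,
              if (x$baseline_mode) " [baseline]" else ""))
  invisible(x)
}

## --- flow field container ---------------------------------------------------

new_flow_field <- function(u, v, w = NULL) {
  structure(list(u = u, v = v, w = w, ndim = if (is.null(w)) 2L else 3L,
                 shape = dim(u)),
            class = "flow_field")
}

#' Create a flow field
#'
#' @param u,v,w Displacement component grids in voxel units (`w = NULL` for
#'   2D fields). `u` displaces along axis 1, `v` axis 2, `w` axis 3.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(u, v, w = NULL) {
  u <- as_volume(u); v <- as_volume(v)
  if (!identical(dim(u), dim(v))) stop("component shapes differ", call. = FALSE)
  if (!is.null(w)) {
    w <- as_volume(w)
    if (!identical(dim(u), dim(w))) stop("component shapes differ", call. = FALSE)
  }
  new_flow_field(u, v, w)
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- flow_magnitude(x)
  cat(sprintf("flow_field (%dD, %s): |w| mean %.4g, max %.4g voxels\n",
              x$ndim, paste(x$shape, collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

#' Flow magnitude
#' @param flow A `flow_field`.
#' @return Grid of Euclidean displacement magnitudes.
#' @export
flow_magnitude <- function(flow) {
  m <- flow$u^2 + flow$v^2
  if (!is.null(flow$w)) m <- m + flow$w^2
  sqrt(m)
}

zero_flow <- function(shape, ndim) {
  z <- array(0, shape)
  new_flow_field(z, z, if (ndim == 3) z else NULL)
}

scale_flow <- function(flow, s) {
  new_flow_field(s * flow$u, s * flow$v,
                 if (is.null(flow$w)) NULL else s * flow$w)
}

## --- pyramid and warping ----------------------------------------------------

#' Multiresolution pyramid
#'
#' Builds a coarse-to-fine pyramid: each level is the previous one low-pass
#' filtered with the Gaussian window and decimated by 2 per axis. The number
#' of levels is clipped (with a warning) so that the coarsest level keeps at
#' least 8 samples per axis.
#'
#' @param volume Numeric matrix or array.
#' @param levels Requested depth (level 1 is the input itself).
#' @return A list of volumes, finest first.
#' @export
build_pyramid <- function(volume, levels) {
  volume <- as_volume(volume)
  max_levels <- 1L
  sz <- dim(volume)
  while (all(ceiling(sz / 2) >= 8) && max_levels < levels) {
    sz <- ceiling(sz / 2)
    max_levels <- max_levels + 1L
  }
  if (max_levels < levels) {
    warning(sprintf("pyramid clipped to %d levels (coarsest level must keep >= 8 samples per axis)",
                    max_levels), call. = FALSE)
    levels <- max_levels
  }
  kern <- window_weights(1.6, 3) # anti-alias std ~1.1 voxels for 2x decimation
  pyr <- vector("list", levels)
  pyr[[1]] <- volume
  for (l in seq_len(levels - 1L)) {
    low <- correlate_separable(pyr[[l]], rep(list(kern), vol_ndim(volume)))
    sub <- lapply(dim(low), function(n) seq(1, n, by = 2))
    pyr[[l + 1]] <- do.call(`[`, c(list(low), sub, list(drop = FALSE)))
  }
  pyr
}

#' Backward warping
#'
#' Resamples a volume at `x + w(x)` with edge clamping: the standard
#' backward-warping step that pulls the second volume of a pair onto the
#' first one's grid. The default separable Catmull-Rom cubic interpolation
#' keeps the passband flat enough for the high-order steered-coefficient
#' constraints to remain consistent under fractional shifts; plain
#' bilinear/trilinear interpolation is available via `method = "linear"`.
#'
#' @param volume Numeric matrix or array.
#' @param flow A `flow_field` of the same shape.
#' @param method `"cubic"` (default) or `"linear"`.
#' @return The warped volume.
#' @export
warp_volume <- function(volume, flow, method = c("cubic", "linear")) {
  method <- match.arg(method)
  volume <- as_volume(volume)
  if (!identical(dim(volume), flow$shape)) {
    stop("flow shape does not match volume", call. = FALSE)
  }
  out <- cpp_warp(as.numeric(volume), as.integer(dim(volume)),
                  as.numeric(flow$u), as.numeric(flow$v),
                  if (is.null(flow$w)) NULL else as.numeric(flow$w),
                  if (method == "cubic") 1L else 0L)
  array(out, dim(volume))
}

upsample_flow <- function(flow, new_shape) {
  up <- function(g) {
    array(cpp_upsample2(as.numeric(g), as.integer(dim(g)),
                        as.integer(new_shape)), new_shape) * 2
  }
  new_flow_field(up(flow$u), up(flow$v),
                 if (is.null(flow$w)) NULL else up(flow$w))
}

## --- data term --------------------------------------------------------------

## Constraint list for one linearization: each constraint has a temporal
## difference grid `it`, Cartesian derivative grids `g` (one per axis) and a
## scalar weight. The derivative grids come from the order-raising property:
## the spatial derivative of a coefficient field is the next-higher-order
## coefficient scaled by sqrt(2 (l+1)) / sigma, evaluated on the *warped*
## second volume; steered constraints raise along the (frozen) steered axes
## and rotate back to Cartesian derivatives.
#' Temporal differences and linearized constraints
#'
#' Computes, for one warp pass, the constancy constraints of the flow
#' energy: the order-0 (intensity) constraint and one constraint per on-axis
#' steered coefficient of orders `1 .. N-1` (order `N` cannot contribute a
#' derivative, which would require order `N + 1` coefficients). Temporal
#' differences subtract the coefficients of the first volume from those of
#' the warped second volume; spatial derivatives use the order-raising
#' property on the warped second volume's coefficients, in the orientation
#' frame estimated from the first volume.
#'
#' @param coeffs_t `hermite_coeffs` of the first volume.
#' @param coeffs_t1_warped `hermite_coeffs` of the warped second volume.
#' @param orientation Orientation field of the first volume.
#' @param params A [flow_params()] object.
#' @return A list of constraints, each with elements `it`, `g` (list of
#'   derivative grids) and `weight`.
#' @export
temporal_differences <- function(coeffs_t, coeffs_t1_warped, orientation,
                                 params) {
  nd <- coeffs_t$ndim
  zero <- idx_name(rep(0L, nd))
  cons <- list()
  ## order-0 intensity constraint
  g0 <- lapply(seq_len(nd), function(a) {
    coefficient_derivative(coeffs_t1_warped, rep(0L, nd), a)
  })
  cons[[1]] <- list(it = coeffs_t1_warped$coeffs[[zero]] - coeffs_t$coeffs[[zero]],
                    g = g0, weight = 1)
  N <- params$order_max
  gamma <- if (params$baseline_mode) 0 else params$gamma
  n_active <- max(N - 1L, 0L)
  if (gamma > 0 && n_active == 0) {
    warning("order_max too low for steered constraints (need N >= 2); ",
            "using the intensity constraint only", call. = FALSE)
  }
  if (gamma > 0 && n_active > 0) {
    gw <- if (params$normalize_gamma) gamma / n_active else gamma
    frame <- orientation_frame(orientation)
    for (n in seq_len(n_active)) {
      on_axis <- c(n, rep(0L, nd - 1L))
      sel <- rowSums(coeffs_t$indices) == n
      idxs <- coeffs_t$indices[sel, , drop = FALSE]
      keys <- apply(idxs, 1, idx_name)
      s1 <- steer_one(coeffs_t$coeffs[keys], idxs, frame, on_axis)
      s2 <- steer_one(coeffs_t1_warped$coeffs[keys], idxs, frame, on_axis)
      ## Cartesian derivative of the steered coefficient: differentiate each
      ## Cartesian coefficient of the block (order-raising identity), then
      ## steer the derivative grids with the same frozen frame.
      g <- lapply(seq_len(nd), function(ax) {
        dgrids <- lapply(seq_len(nrow(idxs)), function(r) {
          coefficient_derivative(coeffs_t1_warped, idxs[r, ], ax)
        })
        steer_one(dgrids, idxs, frame, on_axis)
      })
      ## The on-axis steered coefficients describe the 1D intensity profile
      ## along the local orientation; they carry motion information along
      ## that axis only, so the constraint gradient is projected onto it.
      ## (Un-projected gradients let small cross-orientation inconsistencies
      ## masquerade as confident transverse motion evidence.)
      gp <- 0
      for (a in seq_len(nd)) gp <- gp + g[[a]] * frame$e1[[a]]
      g <- lapply(seq_len(nd), function(a) gp * frame$e1[[a]])
      cons[[length(cons) + 1]] <- list(it = s2 - s1, g = g, weight = gw)
    }
  }
  cons
}

#' Assemble the per-voxel linear system
#'
#' Builds the per-voxel normal equations of the linearized flow energy: the
#' data matrix `J = sum_c weight_c g_c g_c^T` plus `alpha` on the diagonal,
#' and the data right-hand side `r = -sum_c weight_c it_c g_c`. The
#' smoothness term enters at solve time as the Horn-Schunck neighbor-average
#' coupling `alpha * (mean_neighbors(w + dw) - w)`.
#'
#' @param constraints Output of [temporal_differences()].
#' @param params A [flow_params()] object.
#' @return An object of class `linear_system` with grids `A` (matrix
#'   entries, row-major `A1..A9` with `alpha` added on the diagonal) and
#'   `b` (data part of the right-hand side).
#' @export
assemble_system <- function(constraints, params) {
  nd <- length(constraints[[1]]$g)
  shape <- dim(constraints[[1]]$it)
  zero <- array(0, shape)
  J <- list(J11 = zero, J12 = zero, J22 = zero)
  if (nd == 3) J <- c(J, list(J13 = zero, J23 = zero, J33 = zero))
  r <- list(r1 = zero, r2 = zero)
  if (nd == 3) r$r3 <- zero
  for (cst in constraints) {
    w <- cst$weight
    g <- cst$g
    J$J11 <- J$J11 + w * g[[1]]^2
    J$J12 <- J$J12 + w * g[[1]] * g[[2]]
    J$J22 <- J$J22 + w * g[[2]]^2
    r$r1 <- r$r1 - w * cst$it * g[[1]]
    r$r2 <- r$r2 - w * cst$it * g[[2]]
    if (nd == 3) {
      J$J13 <- J$J13 + w * g[[1]] * g[[3]]
      J$J23 <- J$J23 + w * g[[2]] * g[[3]]
      J$J33 <- J$J33 + w * g[[3]]^2
      r$r3 <- r$r3 - w * cst$it * g[[3]]
    }
  }
  structure(list(J = J, b = r, alpha = params$alpha, ndim = nd, shape = shape),
            class = "linear_system")
}

#' Solve for the flow increments
#'
#' Iterates the per-voxel exact (cofactor) solve of the assembled 2x2/3x3
#' systems with the neighbor-average smoothness coupling updated from the
#' previous sweep (a Jacobi iteration over the coupling), until
#' `params$iterations` sweeps or until the mean absolute increment change
#' falls below `params$solver_tolerance`. Degenerate per-voxel matrices are
#' regularized with a tiny diagonal jitter.
#'
#' @param system A [assemble_system()] result.
#' @param params A [flow_params()] object.
#' @param flow Current accumulated flow (`flow_field`), kept fixed.
#' @return A `flow_field` holding the increments `(du, dv, dw)`, with the
#'   per-sweep mean update magnitudes in attribute `"deltas"`.
#' @export
solve_increment <- function(system, params, flow = NULL) {
  if (is.null(flow)) flow <- zero_flow(system$shape, system$ndim)
  w0 <- list(u = as.numeric(flow$u), v = as.numeric(flow$v))
  if (system$ndim == 3) w0$w <- as.numeric(flow$w)
  res <- cpp_flow_solve(lapply(system$J, as.numeric),
                        lapply(system$b, as.numeric), w0,
                        as.integer(system$shape), system$alpha,
                        params$iterations, params$solver_tolerance)
  out <- new_flow_field(array(res$du, system$shape), array(res$dv, system$shape),
                        if (system$ndim == 3) array(res$dw, system$shape) else NULL)
  attr(out, "deltas") <- res$deltas
  attr(out, "iterations") <- res$iterations
  out
}

## --- top-level estimator ----------------------------------------------------

#' Estimate optical flow between two volumes
#'
#' Coarse-to-fine estimation of the dense displacement field between two 2D
#' images or 3D volumes. At each pyramid level and warp pass, both volumes
#' are symmetrically warped by half the current flow (so interpolation
#' attenuates their coefficients equally), Hermite and steered coefficients
#' are recomputed, the linearized energy is minimized for an increment
#' (clamped to `max_increment`), and the flow is updated; between levels the
#' flow is upsampled and rescaled. Steered constraints act on the finest
#' `steered_levels` levels; coarser levels use the intensity term alone.
#'
#' @param volume_t,volume_t1 Two volumes of identical shape (2D or 3D).
#' @param params A [flow_params()] object.
#' @param verbose If `TRUE`, log per-level energies.
#' @return A `flow_field` with the displacement from `volume_t` to
#'   `volume_t1` in voxel units (`warp_volume(volume_t1, flow)` reconstructs
#'   `volume_t`). Per-level data/smoothness energies are in attribute
#'   `"energy"`.
#' @examples
#' v1 <- array(rnorm(16^3), c(16, 16, 16))
#' p <- flow_params(levels = 1, iterations = 10, order_max = 2)
#' f <- estimate_flow(v1, v1, p)
#' max(abs(f$u)) # ~0: identical volumes
#' @export
estimate_flow <- function(volume_t, volume_t1, params = flow_params(),
                          verbose = FALSE) {
  volume_t <- as_volume(volume_t)
  volume_t1 <- as_volume(volume_t1)
  if (!identical(dim(volume_t), dim(volume_t1))) {
    stop("volumes must have identical shapes", call. = FALSE)
  }
  nd <- vol_ndim(volume_t)
  if (!nd %in% 2:3) stop("volumes must be 2D or 3D", call. = FALSE)
  bank <- hermite_filter_bank(params$order_max, params$window_size,
                              sigma = params$sigma, ndim = nd)
  pyr1 <- build_pyramid(volume_t, params$levels)
  pyr2 <- suppressWarnings(build_pyramid(volume_t1, params$levels))
  levels <- length(pyr1)
  flow <- zero_flow(dim(pyr1[[levels]]), nd)
  energy_log <- numeric(0)
  clamp <- function(g) pmin(pmax(g, -params$max_increment), params$max_increment)
  for (lev in rev(seq_len(levels))) {
    if (!identical(flow$shape, dim(pyr1[[lev]]))) {
      flow <- upsample_flow(flow, dim(pyr1[[lev]]))
    }
    level_params <- params
    if (lev > params$steered_levels) level_params$gamma <- 0
    for (wp in seq_len(params$warps_per_level)) {
      ## Symmetric (midpoint) warping: both volumes are resampled by half
      ## the current flow, so interpolation attenuates their coefficients
      ## equally and the temporal differences are unbiased at the solution.
      v1w <- warp_volume(pyr1[[lev]], scale_flow(flow, -0.5))
      v2w <- warp_volume(pyr2[[lev]], scale_flow(flow, +0.5))
      c1 <- hermite_transform(v1w, bank)
      c2 <- hermite_transform(v2w, bank)
      orient <- estimate_orientation(c1)
      cons <- temporal_differences(c1, c2, orient, level_params)
      system <- assemble_system(cons, level_params)
      inc <- solve_increment(system, level_params, flow)
      flow$u <- flow$u + clamp(inc$u)
      flow$v <- flow$v + clamp(inc$v)
      if (nd == 3) flow$w <- flow$w + clamp(inc$w)
    }
    e_data <- sum(vapply(cons, function(cst) cst$weight * mean(cst$it^2), 0))
    energy_log <- c(energy_log, e_data)
    if (verbose) {
      message(sprintf("level %d (%s): mean data energy %.4g", lev,
                      paste(dim(pyr1[[lev]]), collapse = "x"), e_data))
    }
  }
  attr(flow, "energy") <- energy_log
  flow
}
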