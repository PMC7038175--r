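## Synthetic 2D/3D+t phantoms with analytic ground-truth motion: rigid
## translation and in-plane rotation of smooth textured fields, and a
## beating ellipsoidal-shell "ventricle" whose radius follows a cyclic
## contraction/dilation schedule. Every phantom is deterministic given its
## seed, and frames are resampled with the same linear interpolator used by
## the flow estimator's warping step.

#' Phantom specification
#'
#' @param kind One of `"translation"`, `"rotation"`, `"beating_ellipsoid"`.
#' @param shape Integer grid dimensions (length 2 or 3); the beating
#'   ellipsoid requires at least 16 samples per axis.
#' @param amplitude Motion magnitude: per-axis voxel shift per step
#'   (translation; scalar = shift along axis 1), rotation angle in radians
#'   per step, or peak fractional radius contraction of the shell.
#' @param phases Number of time steps (e.g. 10 for cardiac phases 0-90%).
#' @param correlation_length Texture correlation length in voxels.
#' @param contrast Texture intensity standard deviation (stored scale).
#' @param background,foreground Background level and shell peak intensity
#'   (beating ellipsoid), on a CT-like 0-255 stored scale.
#' @param noise_sigma Standard deviation of additive zero-mean Gaussian
#'   noise applied to every frame.
#' @param seed RNG seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("translation", "rotation", "beating_ellipsoid"),
                         shape = c(32, 32, 32), amplitude = NULL, phases = 2,
                         correlation_length = 4, contrast = 40,
                         background = 50, foreground = 200,
                         noise_sigma = 0, seed = 1) {
  kind <- match.arg(kind)
  if (!length(shape) %in% 2:3) stop("'shape' must have length 2 or 3", call. = FALSE)
  if (kind == "beating_ellipsoid" && any(shape < 16)) {
    stop("beating_ellipsoid requires shape >= 16 per axis", call. = FALSE)
  }
  if (is.null(amplitude)) {
    amplitude <- switch(kind, translation = 1, rotation = 0.05,
                        beating_ellipsoid = 0.18)
  }
  structure(list(kind = kind, shape = as.integer(shape), amplitude = amplitude,
                 phases = as.integer(phases),
                 correlation_length = correlation_length, contrast = contrast,
                 background = background, foreground = foreground,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Band-limited Gaussian random field: white noise blurred by a Gaussian of
## scale correlation_length / 2, standardized, then scaled to `contrast`.
smooth_texture <- function(shape, correlation_length, contrast, seed) {
  set.seed(seed)
  x <- array(stats::rnorm(prod(shape)), shape)
  sg <- max(correlation_length / 2, 0.5)
  r <- max(ceiling(2 * sg), 1)
  k <- window_weights(sg * sqrt(2), r) # blur kernel at scale sg per axis
  x <- correlate_separable(x, rep(list(k), length(shape)))
  x <- (x - mean(x)) / stats::sd(x)
  x * contrast
}

## Cosine taper to zero within `margin` voxels of every volume face.
boundary_taper <- function(shape, margin = 4) {
  ramp1 <- function(n) {
    i <- seq_len(n) - 1
    d <- pmin(i, n - 1 - i)
    ifelse(d >= margin, 1, 0.5 * (1 - cos(pi * d / margin)))
  }
  t1 <- ramp1(shape[1])
  out <- array(1, shape)
  if (length(shape) == 3) {
    out <- outer(outer(t1, ramp1(shape[2])), ramp1(shape[3]))
  } else {
    out <- outer(t1, ramp1(shape[2]))
  }
  out
}

## Piecewise-cosine radius scale over the cycle: 1 at phase 0, minimum
## (1 - a_c) at 30% (end-contraction), maximum (1 + a_d) at 70%
## (end-dilation), back to 1 at 100%.
cycle_scale <- function(frac, a_c, a_d = a_c * 0.3) {
  s <- numeric(length(frac))
  for (i in seq_along(frac)) {
    f <- frac[i] %% 1
    if (f <= 0.3) {
      s[i] <- 1 - a_c * (1 - cos(pi * f / 0.3)) / 2
    } else if (f <= 0.7) {
      s[i] <- (1 - a_c) + (a_c + a_d) * (1 - cos(pi * (f - 0.3) / 0.4)) / 2
    } else {
      s[i] <- (1 + a_d) - a_d * (1 - cos(pi * (f - 0.7) / 0.3)) / 2
    }
  }
  s
}

coord_grids <- function(shape) {
  nd <- length(shape)
  lapply(seq_len(nd), function(a) {
    perm <- rep(1, nd); perm[a] <- shape[a]
    g <- array(rep(seq_len(shape[a]) - 1, each = prod(shape[seq_len(a - 1)])),
               shape)
    g
  })
}

## Smooth deterministic angular texture on the unit sphere/circle.
angular_texture <- function(units, seed, nterms = 4) {
  set.seed(seed + 1000L)
  nd <- length(units)
  acc <- 0
  for (t in seq_len(nterms)) {
    w <- stats::rnorm(nd, sd = 2)
    ph <- stats::runif(1, 0, 2 * pi)
    arg <- ph
    for (a in seq_len(nd)) arg <- arg + w[a] * units[[a]]
    acc <- acc + sin(arg) / nterms
  }
  acc
}

#' Generate a phantom sequence with ground-truth flow
#'
#' Produces the frame sequence of a [phantom_spec()] together with the
#' analytic ground-truth flow of every transition, in the package's backward
#' warping convention: `warp_volume(frame[t+1], flow[t])` reconstructs
#' `frame[t]` (up to interpolation).
#'
#' @param spec A `phantom_spec`.
#' @return A list with `volumes` (list of arrays), `flows` (list of
#'   `flow_field`s, one per transition), `spec`, and `cycle_scale` (the
#'   radius schedule, beating ellipsoid only).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("'spec' must be a phantom_spec", call. = FALSE)
  }
  shape <- spec$shape
  nd <- length(shape)
  out <- switch(spec$kind,
    translation = phantom_translation(spec, nd),
    rotation = phantom_rotation(spec, nd),
    beating_ellipsoid = phantom_beating(spec, nd)
  )
  if (spec$noise_sigma > 0) {
    out$volumes <- lapply(seq_along(out$volumes), function(i) {
      add_noise(out$volumes[[i]], spec$noise_sigma,
                seed = spec$seed + 7919L * i)
    })
  }
  out$spec <- spec
  out
}

phantom_translation <- function(spec, nd) {
  shift <- spec$amplitude
  if (length(shift) == 1) shift <- c(shift, rep(0, nd - 1))
  base <- smooth_texture(spec$shape, spec$correlation_length, spec$contrast,
                         spec$seed) + spec$background
  const_flow <- function() {
    comps <- lapply(seq_len(nd), function(a) array(shift[a], spec$shape))
    new_flow_field(comps[[1]], comps[[2]], if (nd == 3) comps[[3]] else NULL)
  }
  volumes <- vector("list", spec$phases)
  for (p in seq_len(spec$phases)) {
    off <- -(p - 1) * shift
    fl <- new_flow_field(array(off[1], spec$shape), array(off[2], spec$shape),
                         if (nd == 3) array(off[3], spec$shape) else NULL)
    volumes[[p]] <- warp_volume(base, fl)
  }
  flows <- lapply(seq_len(spec$phases - 1), function(i) const_flow())
  list(volumes = volumes, flows = flows)
}

phantom_rotation <- function(spec, nd) {
  base <- smooth_texture(spec$shape, spec$correlation_length, spec$contrast,
                         spec$seed) + spec$background
  ctr <- (spec$shape - 1) / 2
  taper <- boundary_taper(spec$shape)
  xg <- coord_grids(spec$shape)
  rot_disp <- function(angle) {
    ## in-plane (axes 1-2) rotation displacement of the coordinate map
    dx <- xg[[1]] - ctr[1]; dy <- xg[[2]] - ctr[2]
    ca <- cos(angle); sa <- sin(angle)
    list(u = (ca * dx - sa * dy) - dx, v = (sa * dx + ca * dy) - dy)
  }
  volumes <- vector("list", spec$phases)
  for (p in seq_len(spec$phases)) {
    d <- rot_disp(-(p - 1) * spec$amplitude)
    fl <- new_flow_field(d$u * taper, d$v * taper,
                         if (nd == 3) array(0, spec$shape) else NULL)
    volumes[[p]] <- warp_volume(base, fl)
  }
  gt <- rot_disp(spec$amplitude)
  flows <- lapply(seq_len(spec$phases - 1), function(i) {
    new_flow_field(gt$u * taper, gt$v * taper,
                   if (nd == 3) array(0, spec$shape) else NULL)
  })
  list(volumes = volumes, flows = flows)
}

phantom_beating <- function(spec, nd) {
  shape <- spec$shape
  ctr <- (shape - 1) / 2
  radii <- 0.30 * (shape - 1) # ellipsoid semi-axes in voxels
  shell_width <- 0.16 # of the radius
  xg <- coord_grids(shape)
  rel <- lapply(seq_len(nd), function(a) (xg[[a]] - ctr[a]))
  rr <- sqrt(Reduce(`+`, lapply(rel, function(g) g^2)))
  rr_safe <- pmax(rr, 1e-6)
  units <- lapply(rel, function(g) g / rr_safe)
  tex <- angular_texture(units, spec$seed)
  frac <- (seq_len(spec$phases) - 1) / spec$phases
  s <- cycle_scale(frac, spec$amplitude)
  make_frame <- function(sp) {
    rho <- sqrt(Reduce(`+`, lapply(seq_len(nd), function(a) {
      (rel[[a]] / (sp * radii[a]))^2
    })))
    shell <- exp(-(rho - 1)^2 / (2 * shell_width^2))
    spec$background + (spec$foreground - spec$background) * shell *
      (1 + 0.3 * tex)
  }
  volumes <- lapply(s, make_frame)
  flows <- lapply(seq_len(spec$phases - 1), function(i) {
    ratio <- s[i + 1] / s[i] - 1
    new_flow_field(ratio * rel[[1]], ratio * rel[[2]],
                   if (nd == 3) ratio * rel[[3]] else NULL)
  })
  list(volumes = volumes, flows = flows, cycle_scale = s)
}

#' Shell mask of the beating-ellipsoid phantom
#'
#' Region where the phantom's shell carries signal at phase `phase`,
#' emulating a segmented left-ventricle mask.
#'
#' @param spec A beating-ellipsoid `phantom_spec`.
#' @param phase Phase index (1-based) at which to take the shell.
#' @param width Half-width of the accepted band in normalized radius units.
#' @return A logical array.
#' @export
phantom_shell_mask <- function(spec, phase = 1, width = 0.35) {
  stopifnot(spec$kind == "beating_ellipsoid")
  shape <- spec$shape
  nd <- length(shape)
  ctr <- (shape - 1) / 2
  radii <- 0.30 * (shape - 1)
  s <- cycle_scale((seq_len(spec$phases) - 1) / spec$phases, spec$amplitude)
  xg <- coord_grids(shape)
  rho <- sqrt(Reduce(`+`, lapply(seq_len(nd), function(a) {
    ((xg[[a]] - ctr[a]) / (s[phase] * radii[a]))^2
  })))
  abs(rho - 1) < width
}

#' Add Gaussian noise to a volume
#'
#' @param volume Numeric matrix or array.
#' @param sigma Non-negative noise standard deviation on the stored
#'   intensity scale; `0` returns the input unchanged.
#' @param seed Optional RNG seed for reproducibility.
#' @return The noisy volume.
#' @export
add_noise <- function(volume, sigma, seed = NULL) {
  volume <- as_volume(volume)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (sigma == 0) return(volume)
  if (!is.null(seed)) set.seed(seed)
  volume + array(stats::rnorm(length(volume), sd = sigma), dim(volume))
}

#' Noise-sweep preset
#'
#' The packaged set of noise standard deviations used by the robustness
#' protocol.
#' @return Numeric vector `c(0, 5, 10, 15, 20, 30)`.
#' @export
noise_sweep_levels <- function() c(0, 5, 10, 15, 20, 30)
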