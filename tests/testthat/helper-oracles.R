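## Shared fixtures and independent oracles for the test suite.

## Band-limited random volume (independent of the synthetic module): white
## noise smoothed by separable moving averages.
smooth_volume <- function(shape, seed = 1, passes = 3) {
  set.seed(seed)
  x <- array(rnorm(prod(shape)), shape)
  k <- rep(1, 5) / 5
  for (p in seq_len(passes)) {
    for (a in seq_along(shape)) x <- hermiteflow:::correlate_axis(x, k, a)
  }
  x / sd(x)
}

## Coordinate grids (0-based), x fastest.
coord_grid <- function(shape, axis) {
  idx <- slice.index(array(0, shape), axis)
  idx - 1
}

## Polynomial volume of given per-term exponents and coefficients.
poly_volume <- function(shape, terms) {
  g <- lapply(seq_along(shape), function(a) coord_grid(shape, a))
  out <- array(0, shape)
  for (tm in terms) {
    mono <- array(tm$coef, shape)
    for (a in seq_along(shape)) mono <- mono * g[[a]]^tm$expo[a]
    out <- out + mono
  }
  out
}

## Symmetric (edge-inclusive) reflection of 1-based indices.
reflect_1based <- function(i, n) {
  i <- i - 1
  while (any(i < 0 | i >= n)) {
    i <- ifelse(i < 0, -i - 1, i)
    i <- ifelse(i >= n, 2 * n - i - 1, i)
  }
  i + 1
}

## Direct (non-separable) N-D correlation with a full kernel, reflected
## boundaries: the brute-force oracle for the separable transform.
direct_correlate <- function(vol, kern) {
  d <- dim(vol)
  nd <- length(d)
  kd <- dim(kern)
  R <- (kd - 1) %/% 2
  out <- array(0, d)
  offs <- as.matrix(expand.grid(lapply(kd, seq_len)))
  for (r in seq_len(nrow(offs))) {
    w <- kern[matrix(offs[r, ], 1)]
    if (w == 0) next
    idx <- lapply(seq_len(nd), function(a) {
      reflect_1based(seq_len(d[a]) + offs[r, a] - R[a] - 1, d[a])
    })
    out <- out + w * do.call(`[`, c(list(vol), idx))
  }
  out
}

## Neighbour mean with replicated (clamped) boundaries, matching the
## solver's discretization.
clamped_neighbor_mean <- function(g) {
  d <- dim(g)
  nd <- length(d)
  acc <- 0
  for (a in seq_len(nd)) {
    lo <- pmax(seq_len(d[a]) - 1, 1)
    hi <- pmin(seq_len(d[a]) + 1, d[a])
    sel <- function(ix) {
      args <- rep(list(quote(expr = )), nd)
      args[[a]] <- ix
      do.call(`[`, c(list(g), args))
    }
    acc <- acc + sel(lo) + sel(hi)
  }
  acc / (2 * nd)
}

## Independent Horn-Schunck solver: given the smoothed-intensity channel and
## its gradient grids, iterate the classical closed-form per-voxel update
## (Sherman-Morrison form of the 3x3 solve) with Jacobi neighbour coupling.
horn_schunck_oracle <- function(it, gx, gy, gz = NULL, alpha, iterations) {
  nd <- if (is.null(gz)) 2 else 3
  d <- dim(it)
  u <- array(0, d); v <- array(0, d)
  w <- if (nd == 3) array(0, d)
  denom <- alpha + gx^2 + gy^2 + if (nd == 3) gz^2 else 0
  for (k in seq_len(iterations)) {
    ub <- clamped_neighbor_mean(u)
    vb <- clamped_neighbor_mean(v)
    wb <- if (nd == 3) clamped_neighbor_mean(w)
    proj <- gx * ub + gy * vb + it # g . nbhd_mean + it
    if (nd == 3) proj <- proj + gz * wb
    u <- ub - gx * proj / denom
    v <- vb - gy * proj / denom
    if (nd == 3) w <- wb - gz * proj / denom
  }
  list(u = u, v = v, w = w)
}

mean_epe <- function(flow, gt, margin = 6) {
  d <- flow$shape
  sq <- (flow$u - gt$u)^2 + (flow$v - gt$v)^2
  if (!is.null(flow$w)) sq <- sq + (flow$w - gt$w)^2
  idx <- lapply(d, function(n) (margin + 1):(n - margin))
  mean(sqrt(do.call(`[`, c(list(sq), idx))))
}

const_flow3 <- function(shape, s) {
  flow_field(array(s[1], shape), array(s[2], shape), array(s[3], shape))
}
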