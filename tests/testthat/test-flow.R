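test_that("pyramid halves shapes and clips to keep 8 samples per axis", {
  vol <- smooth_volume(c(64, 64, 64), seed = 1)
  expect_warning(pyr <- build_pyramid(vol, 5), "clipped")
  expect_length(pyr, 4)
  expect_identical(lapply(pyr, dim),
                   list(c(64L, 64L, 64L), c(32L, 32L, 32L),
                        c(16L, 16L, 16L), c(8L, 8L, 8L)))
  ## constant volume stays constant
  pc <- build_pyramid(array(4, c(32, 32, 32)), 2)
  expect_equal(range(pc[[2]]), c(4, 4), tolerance = 1e-12)
  ## low-pass + decimation never amplifies energy
  for (k in 2:4) expect_lt(mean(pyr[[k]]^2), mean(pyr[[k - 1]]^2) * 1.05)
})

test_that("warping reproduces integer shifts and linear ramps exactly", {
  vol <- smooth_volume(c(16, 16, 16), seed = 2)
  z <- zero <- const_flow3(dim(vol), c(0, 0, 0))
  expect_equal(warp_volume(vol, zero), vol, tolerance = 1e-14)
  for (method in c("cubic", "linear")) {
    ## integer shift vs index-roll oracle on the interior
    fl <- const_flow3(dim(vol), c(1, 0, 0))
    w <- warp_volume(vol, fl, method = method)
    expect_equal(w[1:15, , ], vol[2:16, , ], tolerance = 1e-14)
    ## half-voxel shift of a linear ramp is exact
    ramp <- poly_volume(c(12, 12, 12), list(list(coef = 2, expo = c(1, 0, 0)),
                                            list(coef = 1, expo = c(0, 0, 0))))
    wr <- warp_volume(ramp, const_flow3(dim(ramp), c(0.5, 0, 0)), method = method)
    expect_equal(wr[3:9, , ], ramp[3:9, , ] + 1, tolerance = 1e-12)
  }
  expect_error(warp_volume(vol, const_flow3(c(8, 8, 8), c(0, 0, 0))), "shape")
})

test_that("temporal differences vanish for static pairs and isolate DC shifts", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  vol <- smooth_volume(c(14, 14, 14), seed = 3)
  co <- hermite_transform(vol, bank)
  orient <- estimate_orientation(co)
  p <- flow_params()
  cons <- temporal_differences(co, co, orient, p)
  expect_length(cons, 1 + (p$order_max - 1))
  for (cst in cons) expect_lt(max(abs(cst$it)), 1e-12)
  ## second volume shifted by a constant: DC difference only
  co2 <- hermite_transform(vol + 3, bank)
  cons2 <- temporal_differences(co, co2, orient, p)
  expect_equal(cons2[[1]]$it, array(3, dim(vol)), tolerance = 1e-10)
  for (k in 2:length(cons2)) expect_lt(max(abs(cons2[[k]]$it)), 1e-9)
})

test_that("gamma = 0 assembly reduces to the Horn-Schunck normal equations", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  v1 <- smooth_volume(c(12, 12, 12), seed = 4)
  v2 <- smooth_volume(c(12, 12, 12), seed = 5)
  c1 <- hermite_transform(v1, bank)
  c2 <- hermite_transform(v2, bank)
  p <- flow_params(baseline_mode = TRUE)
  cons <- temporal_differences(c1, c2, estimate_orientation(c1), p)
  expect_length(cons, 1)
  sys <- assemble_system(cons, p)
  gx <- coefficient_derivative(c2, c(0L, 0L, 0L), 1)
  gy <- coefficient_derivative(c2, c(0L, 0L, 0L), 2)
  it <- c2$coeffs[["000"]] - c1$coeffs[["000"]]
  expect_equal(sys$J$J11, gx^2, tolerance = 1e-12)
  expect_equal(sys$J$J12, gx * gy, tolerance = 1e-12)
  expect_equal(sys$b$r1, -it * gx, tolerance = 1e-12)
  ## zero volumes: no data, rhs zero
  cz <- hermite_transform(array(0, c(8, 8, 8)), bank)
  sysz <- assemble_system(temporal_differences(cz, cz, estimate_orientation(cz), p), p)
  expect_equal(max(abs(sysz$J$J11)), 0)
  expect_equal(max(abs(sysz$b$r1)), 0)
})

test_that("the increment solver matches direct elimination on a single voxel", {
  set.seed(6)
  g <- matrix(rnorm(9), 3)
  Jm <- crossprod(g) + diag(0.5, 3)
  r <- rnorm(3)
  one <- function(x) array(x, c(1, 1, 1))
  sys <- structure(list(
    J = list(J11 = one(Jm[1, 1]), J12 = one(Jm[1, 2]), J22 = one(Jm[2, 2]),
             J13 = one(Jm[1, 3]), J23 = one(Jm[2, 3]), J33 = one(Jm[3, 3])),
    b = list(r1 = one(r[1]), r2 = one(r[2]), r3 = one(r[3])),
    alpha = 2, ndim = 3L, shape = c(1L, 1L, 1L)), class = "linear_system")
  p <- flow_params(alpha = 2, iterations = 500, solver_tolerance = 0)
  inc <- solve_increment(sys, p)
  ## on one voxel the neighbour mean equals the centre, so alpha cancels at
  ## the fixed point: J d = r
  ref <- solve(Jm, r)
  expect_equal(c(inc$u, inc$v, inc$w), ref, tolerance = 1e-10)
})

test_that("pure smoothness drives the total flow toward a harmonic field", {
  d <- c(8, 8, 8)
  z <- array(0, d)
  sys <- structure(list(
    J = list(J11 = z, J12 = z, J22 = z, J13 = z, J23 = z, J33 = z),
    b = list(r1 = z, r2 = z, r3 = z),
    alpha = 10, ndim = 3L, shape = d), class = "linear_system")
  set.seed(7)
  w0 <- flow_field(array(rnorm(prod(d)), d), z, z)
  p <- flow_params(iterations = 4000, solver_tolerance = 0)
  inc <- solve_increment(sys, p, w0)
  total <- w0$u + inc$u
  resid <- clamped_neighbor_mean(total) - total
  expect_lt(max(abs(resid)), 1e-3 * diff(range(w0$u)))
})

test_that("solver updates converge monotonically on a smooth fixture", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  v1 <- smooth_volume(c(12, 12, 12), seed = 8)
  v2 <- smooth_volume(c(12, 12, 12), seed = 9)
  p <- flow_params(iterations = 40, solver_tolerance = 0)
  cons <- temporal_differences(hermite_transform(v1, bank),
                               hermite_transform(v2, bank),
                               estimate_orientation(hermite_transform(v1, bank)), p)
  inc <- solve_increment(assemble_system(cons, p), p)
  deltas <- attr(inc, "deltas")
  expect_gt(length(deltas), 10)
  expect_lt(deltas[length(deltas)], 0.5 * deltas[1])
  expect_true(all(diff(deltas) < 0.05 * deltas[1]))
})

test_that("identical volumes give zero flow", {
  vol <- smooth_volume(c(20, 20, 20), seed = 10)
  p <- flow_params(levels = 2, iterations = 20)
  fl <- suppressWarnings(estimate_flow(vol, vol, p))
  expect_lt(max(flow_magnitude(fl)), 1e-3)
})

test_that("a translated blob's motion is recovered within 0.2 voxels", {
  d <- c(24, 24, 24)
  g <- lapply(1:3, function(a) coord_grid(d, a) - 11.5)
  blob <- 100 * exp(-(g[[1]]^2 + g[[2]]^2 + g[[3]]^2) / (2 * 4^2))
  v1 <- blob
  v2 <- warp_volume(blob, const_flow3(d, c(-1, 0, 0))) # content moves +1 in x
  fl <- suppressWarnings(estimate_flow(v1, v2, flow_params(levels = 2)))
  supp <- blob > 10
  expect_lt(mean(abs(fl$u[supp] - 1)), 0.2)
  expect_lt(mean(abs(fl$v[supp])), 0.2)
  expect_lt(mean(abs(fl$w[supp])), 0.2)
})

test_that("axis permutation permutes the recovered flow components", {
  ph <- generate_phantom(phantom_spec("translation", shape = c(20, 20, 20),
                                      amplitude = 0.8, phases = 2, seed = 11))
  p <- flow_params(levels = 1, iterations = 30, baseline_mode = TRUE)
  f1 <- estimate_flow(ph$volumes[[1]], ph$volumes[[2]], p)
  f2 <- estimate_flow(aperm(ph$volumes[[1]], c(2, 1, 3)),
                      aperm(ph$volumes[[2]], c(2, 1, 3)), p)
  expect_equal(f2$v, aperm(f1$u, c(2, 1, 3)), tolerance = 1e-8)
  expect_equal(f2$u, aperm(f1$v, c(2, 1, 3)), tolerance = 1e-8)
  expect_equal(f2$w, aperm(f1$w, c(2, 1, 3)), tolerance = 1e-8)
})

test_that("stronger smoothness weight reduces the flow's total variation", {
  ph <- generate_phantom(phantom_spec("beating_ellipsoid", shape = c(24, 24, 24),
                                      phases = 4, seed = 12))
  tv <- function(fl) {
    s <- 0
    for (g in list(fl$u, fl$v, fl$w)) {
      for (a in 1:3) s <- s + sum(abs(hermiteflow:::correlate_axis(g, c(-0.5, 0, 0.5), a)))
    }
    s
  }
  p1 <- flow_params(alpha = 10, levels = 2, iterations = 30)
  p2 <- flow_params(alpha = 80, levels = 2, iterations = 30)
  f1 <- suppressWarnings(estimate_flow(ph$volumes[[1]], ph$volumes[[2]], p1))
  f2 <- suppressWarnings(estimate_flow(ph$volumes[[1]], ph$volumes[[2]], p2))
  expect_lt(tv(f2), tv(f1))
})

test_that("flow parameter validation rejects impossible settings", {
  expect_error(flow_params(alpha = 0), "alpha")
  expect_error(flow_params(gamma = -1), "gamma")
  expect_error(flow_params(levels = 0), "levels")
  expect_error(estimate_flow(array(0, c(8, 8)), array(0, c(9, 9))), "identical shapes")
  expect_error(estimate_flow(array(0, 8), array(0, 8)), "2D or 3D")
})
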