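test_that("angular functions obey the binomial normalization identity", {
  expect_equal(angular_function(0, 0, 1.3), 1)
  expect_equal(angular_function(1, 1, 0), 1)
  expect_equal(angular_function(1, 1, pi / 2), 0, tolerance = 1e-15)
  for (k in 1:5) {
    for (ang in seq(-pi, pi, length.out = 17)) {
      s <- sum(vapply(0:k, function(j) angular_function(j, k, ang)^2, 0))
      expect_equal(s, 1, tolerance = 1e-12)
    }
  }
  expect_error(angular_function(3, 2, 0), "j <= k")
})

test_that("orientation angles follow the quadrant-aware gradient phase", {
  bank <- hermite_filter_bank(2, 5, ndim = 3)
  mk <- function(gx, gy, gz) {
    co <- hermite_transform(array(0, c(4, 4, 4)), bank)
    co$coeffs[["100"]][] <- gx
    co$coeffs[["010"]][] <- gy
    co$coeffs[["001"]][] <- gz
    co
  }
  o <- estimate_orientation(mk(1, 0, 0))
  expect_equal(o$theta[1], 0)
  expect_equal(o$phi[1], pi / 2)
  o <- estimate_orientation(mk(1, 1, 0))
  expect_equal(o$theta[1], pi / 4)
  o <- estimate_orientation(mk(-1, 0, 0))
  expect_equal(abs(o$theta[1]), pi)
  ## degenerate convention
  o <- estimate_orientation(mk(0, 0, 0))
  expect_equal(o$theta[1], 0)
  expect_equal(o$phi[1], 0)
  expect_equal(o$energy[1], 0)
  co <- mk(1, 0, 0)
  co$coeffs[["100"]] <- NULL
  expect_error(estimate_orientation(co), "first-order")
})

random_coeffs <- function(shape = c(6, 6, 6), order_max = 4, seed = 1) {
  bank <- hermite_filter_bank(order_max, 2 * order_max + 1, ndim = length(shape))
  co <- hermite_transform(array(0, shape), bank)
  set.seed(seed)
  for (nm in names(co$coeffs)) co$coeffs[[nm]] <- array(rnorm(prod(shape)), shape)
  co
}

test_that("steering at the reference angles is the identity on all orders", {
  co <- random_coeffs()
  shape <- dim(co$coeffs[[1]])
  orient <- structure(list(theta = array(0, shape), phi = array(pi / 2, shape),
                           energy = array(1, shape), ndim = 3L),
                      class = "orientation_field")
  st <- steer_coefficients(co, orient)
  for (nm in names(co$coeffs)) {
    expect_equal(st$coeffs[[nm]], co$coeffs[[nm]], tolerance = 1e-12)
  }
})

test_that("steering conserves energy within every order", {
  co <- random_coeffs(seed = 2)
  shape <- dim(co$coeffs[[1]])
  set.seed(3)
  orient <- structure(list(theta = array(runif(prod(shape), -pi, pi), shape),
                           phi = array(runif(prod(shape), 0, pi), shape),
                           energy = array(1, shape), ndim = 3L),
                      class = "orientation_field")
  st <- steer_coefficients(co, orient)
  for (n in 0:co$order_max) {
    sel <- which(rowSums(co$indices) == n)
    e_cart <- Reduce(`+`, lapply(sel, function(r) co$coeffs[[r]]^2))
    e_st <- Reduce(`+`, lapply(sel, function(r) st$coeffs[[r]]^2))
    expect_lt(max(abs(e_st - e_cart)) / max(e_cart), 1e-10)
  }
  ## 2D variant
  co2 <- random_coeffs(shape = c(7, 7), order_max = 3, seed = 4)
  orient2 <- structure(list(theta = array(runif(49, -pi, pi), c(7, 7)),
                            phi = NULL, energy = array(1, c(7, 7)), ndim = 2L),
                       class = "orientation_field")
  st2 <- steer_coefficients(co2, orient2)
  for (n in 0:3) {
    sel <- which(rowSums(co2$indices) == n)
    e_cart <- Reduce(`+`, lapply(sel, function(r) co2$coeffs[[r]]^2))
    e_st <- Reduce(`+`, lapply(sel, function(r) st2$coeffs[[r]]^2))
    expect_lt(max(abs(e_st - e_cart)) / max(e_cart), 1e-10)
  }
})

test_that("steering to the local orientation concentrates first-order energy", {
  bank <- hermite_filter_bank(2, 5, ndim = 3)
  vol <- smooth_volume(c(14, 14, 14), seed = 5)
  co <- hermite_transform(vol, bank)
  orient <- estimate_orientation(co)
  st <- steer_coefficients(co, orient)
  on_axis <- st$coeffs[["100"]]
  expect_equal(on_axis, orient$energy, tolerance = 1e-10)
  expect_lt(max(abs(st$coeffs[["010"]])), 1e-10 * max(abs(on_axis)))
  expect_lt(max(abs(st$coeffs[["001"]])), 1e-10 * max(abs(on_axis)))
})

test_that("first-order steering matches an explicit rotation-matrix oracle", {
  co <- random_coeffs(shape = c(5, 5, 5), order_max = 1, seed = 6)
  shape <- c(5, 5, 5)
  set.seed(7)
  theta <- array(runif(prod(shape), -pi, pi), shape)
  phi <- array(runif(prod(shape), 0, pi), shape)
  orient <- structure(list(theta = theta, phi = phi,
                           energy = array(1, shape), ndim = 3L),
                      class = "orientation_field")
  st <- steer_coefficients(co, orient)
  for (probe in list(c(1, 1, 1), c(3, 2, 5), c(5, 5, 1))) {
    i <- probe[1]; j <- probe[2]; k <- probe[3]
    th <- theta[i, j, k]; ph <- phi[i, j, k]
    R <- rbind(
      c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph)),
      c(-sin(th), cos(th), 0),
      c(-cos(ph) * cos(th), -cos(ph) * sin(th), sin(ph))
    )
    v <- c(co$coeffs[["100"]][i, j, k], co$coeffs[["010"]][i, j, k],
           co$coeffs[["001"]][i, j, k])
    got <- c(st$coeffs[["100"]][i, j, k], st$coeffs[["010"]][i, j, k],
             st$coeffs[["001"]][i, j, k])
    expect_equal(got, as.numeric(R %*% v), tolerance = 1e-12)
  }
})

test_that("steering validates grid shapes", {
  co <- random_coeffs(shape = c(5, 5, 5), order_max = 1)
  orient <- structure(list(theta = array(0, c(4, 4, 4)), phi = array(0, c(4, 4, 4)),
                           energy = array(0, c(4, 4, 4)), ndim = 3L),
                      class = "orientation_field")
  expect_error(steer_coefficients(co, orient), "match")
})
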