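test_that("hermite polynomials satisfy the Rodrigues recurrence", {
  x <- seq(-3, 3, by = 0.5)
  expect_equal(hermite_polynomial(0, x), rep(1, length(x)))
  expect_equal(hermite_polynomial(1, x, sigma = 2), 2 * x / 2)
  ## independent recurrence oracle: H_{l+1} = 2 t H_l - 2 l H_{l-1}
  t <- x
  h <- list(rep(1, length(t)), 2 * t)
  for (l in 1:5) h[[l + 2]] <- 2 * t * h[[l + 1]] - 2 * l * h[[l]]
  expect_equal(hermite_polynomial(2, x), 4 * x^2 - 2)
  for (l in 0:6) expect_equal(hermite_polynomial(l, x), h[[l + 1]])
  expect_error(hermite_polynomial(-1, x), "non-negative")
  expect_error(hermite_polynomial(2, x, sigma = 0), "positive")
})

test_that("filter bank has the expected layout and validation", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  expect_s3_class(bank, "hermite_bank")
  expect_identical(nrow(bank$indices), 35L) # (N+1)(N+2)(N+3)/6
  expect_identical(dim(hermite_filter(bank, c(2, 1, 1))), c(5L, 5L, 5L))
  ## order-0 filter: squared-Gaussian window, positive, unit DC gain
  f0 <- hermite_filter(bank, c(0, 0, 0))
  expect_true(all(f0 > 0))
  expect_equal(sum(f0), 1, tolerance = 1e-12)
  ## 2D bank: (N+1)(N+2)/2 filters
  expect_identical(nrow(hermite_filter_bank(3, 5, ndim = 2)$indices), 10L)
  expect_error(hermite_filter_bank(9, 5), "N <= 2")
  expect_error(hermite_filter_bank(4, 4), "odd")
  expect_error(hermite_filter_bank(4, 5, sigma = -1), "positive")
})

test_that("1D kernels are discretely orthonormal under the window", {
  for (M in c(5, 7, 9)) {
    bank <- hermite_filter_bank(min(4, M - 1), M, ndim = 1)
    gram <- t(bank$polynomials) %*% diag(bank$window) %*% bank$polynomials
    expect_equal(gram, diag(nrow(gram)), tolerance = 1e-10)
  }
})

test_that("separable transform equals direct N-D convolution", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  vol <- array(rnorm(12^3), c(12, 12, 12))
  co <- hermite_transform(vol, bank)
  for (r in seq_len(nrow(bank$indices))) {
    idx <- bank$indices[r, ]
    kern <- hermiteflow:::correlation_kernel(bank, idx)
    ref <- direct_correlate(vol, kern)
    got <- co$coeffs[[paste0(idx, collapse = "")]]
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-10)
  }
  ## 2D spot-check
  bank2 <- hermite_filter_bank(3, 5, ndim = 2)
  img <- matrix(rnorm(20^2), 20, 20)
  co2 <- hermite_transform(img, bank2)
  k21 <- hermiteflow:::correlation_kernel(bank2, c(2, 1))
  expect_lt(max(abs(co2$coeffs[["21"]] - direct_correlate(img, k21))), 1e-10)
})

test_that("constant and ramp volumes decompose as expected", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  co <- hermite_transform(array(3.5, c(10, 10, 10)), bank)
  expect_equal(range(co$coeffs[["000"]]), c(3.5, 3.5))
  other <- vapply(co$coeffs[-1], function(g) max(abs(g)), 0)
  expect_lt(max(other), 1e-12)
  ## pure x-ramp: only orders (0,0,0) and (1,0,0) respond in the interior
  ramp <- poly_volume(c(12, 12, 12), list(list(coef = 0.5, expo = c(1, 0, 0))))
  cr <- hermite_transform(ramp, bank)
  m <- 4:9
  for (r in seq_len(nrow(bank$indices))) {
    nm <- paste0(bank$indices[r, ], collapse = "")
    vals <- cr$coeffs[[nm]][m, m, m]
    if (nm %in% c("000", "100")) expect_gt(max(abs(vals)), 1e-6)
    else expect_lt(max(abs(vals)), 1e-10)
  }
})

test_that("forward+inverse reproduces polynomials up to order N exactly", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  shape <- c(14, 14, 14)
  vol <- poly_volume(shape, list(
    list(coef = 2, expo = c(0, 0, 0)),
    list(coef = 0.3, expo = c(1, 0, 0)),
    list(coef = -0.05, expo = c(0, 2, 0)),
    list(coef = 0.01, expo = c(1, 1, 1)),
    list(coef = 0.002, expo = c(2, 0, 2)),
    list(coef = -0.0004, expo = c(0, 1, 3))
  ))
  rec <- hermite_reconstruct(hermite_transform(vol, bank))
  m <- 5:10 # interior: 2x kernel radius from each face
  expect_lt(max(abs((rec - vol)[m, m, m])), 1e-8 * max(abs(vol)))
  ## round-trip of a constant
  rc <- hermite_reconstruct(hermite_transform(array(7, c(10, 10, 10)), bank))
  expect_equal(rc[3:8, 3:8, 3:8], array(7, c(6, 6, 6)), tolerance = 1e-12)
})

test_that("smooth-volume reconstruction error stays below 5 percent", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  vol <- smooth_volume(c(16, 16, 16), seed = 4)
  rec <- hermite_reconstruct(hermite_transform(vol, bank))
  m <- 5:12
  rel <- sqrt(mean((rec - vol)[m, m, m]^2)) / sqrt(mean(vol[m, m, m]^2))
  expect_lt(rel, 0.05)
})

test_that("DC isolation: adding a constant only shifts the order-0 grid", {
  bank <- hermite_filter_bank(3, 5, ndim = 3)
  vol <- smooth_volume(c(12, 12, 12), seed = 5)
  c1 <- hermite_transform(vol, bank)
  c2 <- hermite_transform(vol + 2.5, bank)
  expect_equal(c2$coeffs[["000"]], c1$coeffs[["000"]] + 2.5, tolerance = 1e-12)
  for (nm in names(c1$coeffs)[-1]) {
    expect_lt(max(abs(c2$coeffs[[nm]] - c1$coeffs[[nm]])), 1e-10)
  }
})

test_that("orders up to 3 dominate the AC energy of natural-image-like input", {
  bank <- hermite_filter_bank(4, 5, ndim = 2)
  img <- smooth_volume(c(64, 64), seed = 6)
  co <- hermite_transform(img, bank)
  ord <- rowSums(co$indices)
  energy <- vapply(seq_along(co$coeffs), function(r) sum(co$coeffs[[r]]^2), 0)
  ac_low <- sum(energy[ord >= 1 & ord <= 3])
  ac_all <- sum(energy[ord >= 1])
  expect_gt(ac_low / ac_all, 0.7)
})

test_that("subsampled transform keeps coherent shapes and reconstructs", {
  bank <- hermite_filter_bank(2, 5, ndim = 3)
  vol <- smooth_volume(c(17, 16, 15), seed = 7)
  co <- hermite_transform(vol, bank, stride = 2)
  expect_identical(dim(co$coeffs[[1]]), c(9L, 8L, 8L))
  expect_true(all(vapply(co$coeffs, function(g) identical(dim(g), c(9L, 8L, 8L)), TRUE)))
  rec <- hermite_reconstruct(co)
  expect_identical(dim(rec), dim(vol))
  m <- 5:11
  rel <- sqrt(mean((rec - vol)[m, m, m]^2)) / sqrt(mean(vol[m, m, m]^2))
  expect_lt(rel, 0.25) # subsampled synthesis is approximate
  expect_error(hermite_transform(vol, bank, stride = 30), "stride")
})

test_that("coefficient derivatives track finite differences on smooth fields", {
  bank <- hermite_filter_bank(4, 5, ndim = 3)
  vol <- smooth_volume(c(20, 20, 20), seed = 8, passes = 5)
  co <- hermite_transform(vol, bank)
  m <- 5:16
  for (a in 1:3) {
    dgrid <- coefficient_derivative(co, c(0L, 0L, 0L), a)
    fd <- hermiteflow:::correlate_axis(co$coeffs[["000"]], c(-0.5, 0, 0.5), a)
    rel <- sqrt(mean((dgrid - fd)[m, m, m]^2)) / sqrt(mean(fd[m, m, m]^2))
    expect_lt(rel, 0.05)
  }
  expect_error(coefficient_derivative(co, c(2L, 1L, 1L), 1), "order_max")
})

test_that("reconstruction demands a complete coefficient set", {
  bank <- hermite_filter_bank(2, 5, ndim = 2)
  co <- hermite_transform(matrix(rnorm(64), 8, 8), bank)
  co$coeffs[["11"]] <- NULL
  expect_error(hermite_reconstruct(co), "missing coefficient")
})
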