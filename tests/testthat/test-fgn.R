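test_that("fGn autocovariance matches the closed form at lags 0..5", {
  # oracle: the increment covariance of a process with <X^2(n)> = n^(2H),
  # gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H)/2, written out directly here
  H <- 0.75
  gam <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                              abs(k - 1)^(2 * H))
  expect_equal(fgn_acvf(0:5, H), gam(0:5))
  expect_equal(fgn_acvf(1, 0.75), 2^0.5 - 1)   # = 0.41421...
  x <- fgn(2^19, H, seed = 3)
  for (k in 0:5) expect_equal(acvf0(x, k), gam(k), tolerance = 0.015)
})

test_that("H = 0.5 gives uncorrelated unit normals", {
  x <- fgn(2^18, 0.5, seed = 4)
  expect_equal(sd(x), 1, tolerance = 0.01)
  expect_equal(acvf0(x, 1), 0, tolerance = 0.01)
  expect_gt(shapiro.test(x[1:5000])$p.value, 0.01)
})

test_that("partial sums of fGn diffuse as n^(2H)", {
  # Monte-Carlo: ensemble variance of the cumulative sum at several n
  set.seed(5)
  ns <- c(10, 100, 1000)
  v <- rowMeans(replicate(1000, cumsum(fgn(1000, 0.6))[ns]^2))
  expect_equal(loglog_slope(ns, v), 1.2, tolerance = 0.05)
})

test_that("circulant and Mandelbrot-van Ness generators agree in law", {
  # both series are long-range correlated, so thin to near-independent
  # subsamples before the two-sample tests
  a <- fgn(2^16, 0.7, method = "circulant", seed = 31)
  b <- fgn(2^16, 0.7, method = "mvn", seed = 32)
  th <- seq(1, 2^16, by = 64)
  expect_gt(suppressWarnings(ks.test(a[th], b[th]))$p.value, 0.01)
  # lag-1 pair statistic: sums of consecutive values probe the correlation
  expect_gt(suppressWarnings(ks.test(a[th] + a[th + 1],
                                     b[th] + b[th + 1]))$p.value, 0.01)
})

test_that("spectral generator has power-law ensemble autocorrelation", {
  # eta = 2 - 2H = 0.8: ensemble autocorrelation ~ t^(-0.8) inside the band.
  # Oracle: the band-limited correlation integral E[cos(omega*t)] under the
  # drawn spectral density, computed by numerical quadrature.
  # the power-law window of the band [2*pi/n, pi] covers lags well inside
  # 1/omega_min = n/(2*pi), so probe lags much shorter than that
  set.seed(6)
  n <- 8192
  eta <- 0.8
  band <- c(2 * pi / n, pi)
  norm <- integrate(function(w) w^(eta - 1), band[1], band[2])$value
  phi <- function(t) integrate(function(w) cos(w * t) * w^(eta - 1) / norm,
                               band[1], band[2], subdivisions = 5000L)$value
  lags <- c(2, 4, 8, 16)
  ac <- rowMeans(replicate(200, {
    x <- fgn_spectral(n, H = 0.6, n_modes = 400)
    vapply(lags, function(k) acvf0(x, k), 0)
  }))
  th <- vapply(lags, phi, 0)
  expect_lt(max(abs(ac - th)), 0.01)
  # and the theoretical band-limited decay is the t^(-eta) power law
  expect_equal(loglog_slope(lags, th), -eta, tolerance = 0.1)
})

test_that("spectral generator degenerate and deterministic cases", {
  expect_message(z <- fgn_spectral(100, 0.6, n_modes = 0), "zero series")
  expect_identical(z, numeric(100))
  expect_identical(fgn_spectral(500, 0.75, n_modes = 50, seed = 9),
                   fgn_spectral(500, 0.75, n_modes = 50, seed = 9))
})

test_that("generators are bit-reproducible and validate H", {
  for (m in c("circulant", "mvn", "spectral"))
    expect_identical(fgn(256, 0.8, method = m, seed = 10),
                     fgn(256, 0.8, method = m, seed = 10))
  expect_error(fgn(100, 0), "H")
  expect_error(fgn(100, 1), "H")
})
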