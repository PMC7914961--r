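test_that("trajectory is the cumulative sum of the signal", {
  expect_equal(diffusion_trajectory(c(1, -1, 1)), c(1, 0, 1))
  expect_equal(diffusion_trajectory(numeric(5)), numeric(5))
  x <- rnorm(100)
  expect_equal(diffusion_trajectory(x)[100], sum(x))
  expect_error(diffusion_trajectory(numeric(0)), "empty")
})

test_that("mobile windows produce stride-1 displacement ensembles", {
  X <- c(1, 0, 1, 2)
  expect_equal(window_displacements(X, 2), c(0, 2))
  expect_length(window_displacements(X, 3), 1)      # l = length-1
  expect_equal(window_displacements(rep(5, 10), 4), rep(0, 6))
  X2 <- cumsum(rnorm(500))
  expect_length(window_displacements(X2, 20), 480)
  expect_error(window_displacements(X, 4), "l")
})

test_that("histogram entropy matches hand-computable cases", {
  # four equally occupied bins
  expect_equal(entropy_hist(c(0.1, 1.1, 2.1, 3.1), 1), log(4))
  # all mass in one bin
  expect_equal(entropy_hist(c(0.2, 0.3, 0.4), 1), 0)
  # large-sample standard normal, bin width 0.1:
  # 0.5*log(2*pi*e) - log(0.1) = 3.72152...
  set.seed(21)
  S <- entropy_hist(rnorm(1e6), 0.1)
  expect_equal(S, 0.5 * log(2 * pi * exp(1)) - log(0.1), tolerance = 0.005)
  expect_error(entropy_hist(1, 0.1), "at least 2")
  expect_error(entropy_hist(1:5, 0), "bin_width")
})

test_that("entropy is non-negative and bounded by log(occupied bins)", {
  set.seed(22)
  for (i in 1:20) {
    y <- rt(500, df = sample(1:5, 1)) * 10^runif(1, -1, 1)
    w <- 10^runif(1, -1, 0.5)
    S <- entropy_hist(y, w)
    k <- length(unique(floor(y / w)))
    expect_gte(S, 0)
    expect_lte(S, log(k) + 1e-12)
  }
})

test_that("entropy curves are translation invariant and scale covariant", {
  set.seed(23)
  X <- cumsum(rnorm(20000))
  l <- l_grid(20000, l_min = 10, l_max = 200)
  a <- dea_curve(X, l = l, bin_width = 0.5)
  b <- dea_curve(X + 17.3, l = l, bin_width = 0.5)        # translate
  expect_equal(a$S, b$S)
  cc <- dea_curve(3 * X, l = l, bin_width = 1.5)          # rescale both
  expect_equal(a$S, cc$S)
})

test_that("Gaussian diffusion entropy grows by half the log window ratio", {
  set.seed(24)
  X <- diffusion_trajectory(rnorm(2e5))
  cv <- dea_curve(X, l = c(100, 400, 1600), bin_width = 1)
  expect_equal(cv$S[2] - cv$S[1], 0.5 * log(4), tolerance = 0.03)
  expect_equal(cv$S[3] - cv$S[2], 0.5 * log(4), tolerance = 0.03)
})

test_that("default window grid is log-spaced within sane limits", {
  l <- l_grid(1e6)
  expect_true(all(diff(l) > 0))
  expect_equal(min(l), 10)
  expect_equal(max(l), 1e4)
  expect_error(l_grid(500), "too short")
})
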