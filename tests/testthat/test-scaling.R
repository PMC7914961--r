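test_that("an exact line is recovered to machine precision", {
  l <- c(10, 100, 1000)
  f <- fit_delta(data.frame(l = l, S = 1 + 0.75 * log(l)))
  expect_equal(f$delta, 0.75, tolerance = 1e-12)
  expect_equal(f$A, 1, tolerance = 1e-12)
  expect_equal(f$se, 0, tolerance = 1e-8)
  expect_equal(f$n_points, 3)
})

test_that("rescaling the window unit changes only the intercept", {
  l <- exp(seq(log(10), log(1e4), length.out = 12))
  S <- 0.3 + 0.6 * log(l) + rnorm(12, sd = 1e-3)
  f1 <- fit_delta(data.frame(l = l, S = S))
  f2 <- fit_delta(data.frame(l = 5 * l, S = S))
  expect_equal(f1$delta, f2$delta, tolerance = 1e-10)
  expect_equal(f2$A, f1$A - f1$delta * log(5), tolerance = 1e-10)
})

test_that("fit range restriction and degenerate ranges error cleanly", {
  cv <- data.frame(l = c(5, 10, 50, 100, 500), S = log(c(5, 10, 50, 100, 500)))
  f <- fit_delta(cv, 10, 100)
  expect_equal(f$n_points, 3)
  expect_error(fit_delta(cv, 40, 60), "at least 3")
  expect_error(fit_delta(cv, 100, 10), "l_min")
})

test_that("Gaussian diffusion fit yields the ordinary index", {
  set.seed(41)
  f <- dea(sample(c(-1, 1), 1e5, replace = TRUE))
  expect_lt(abs(f$delta - 0.5), 0.03)
  set.seed(42)
  g <- dea(rnorm(1e5))
  expect_lt(abs(g$delta - 0.5), 0.05)
})

test_that("crucial-event prediction follows both branches and is continuous", {
  expect_equal(delta_crucial(2.5), 2 / 3)
  expect_equal(delta_crucial(1.8), 0.8)
  expect_equal(delta_crucial(2 - 1e-9), 1, tolerance = 1e-8)
  expect_equal(delta_crucial(2 + 1e-9), 1, tolerance = 1e-8)
  # continuous on (1,3) with maximum 1 at mu = 2
  mus <- seq(1.05, 2.95, by = 0.05)
  d <- vapply(mus, delta_crucial, 0)
  expect_true(all(diff(d)[mus[-1] <= 2] > 0))
  expect_true(all(diff(d)[mus[-1] > 2] < 0))
  expect_equal(max(d), 1, tolerance = 0.06)
  expect_error(delta_crucial(3.2), "mu")
  expect_equal(delta_crucial(3.2, allow_ordinary = TRUE), 0.5)
})

test_that("fractional-equation prediction reduces to its limits", {
  expect_equal(delta_fde(0.5, 1), 0.5)      # ordinary diffusion
  expect_equal(delta_fde(0.6, 0.8), 0.5)    # (2*0.6 - 1 + 0.8)/2
  for (H in c(0.2, 0.5, 0.8))
    expect_equal(delta_fde(H, 1), H)        # alpha = 1 is the fBm limit
  # H = 0.5 gives alpha/2, the symmetric-step CTRW scaling (mu-1)/2
  for (a in c(0.3, 0.7))
    expect_equal(delta_fde(0.5, a), a / 2)
  expect_error(delta_fde(0.5, 1.2), "alpha")
  expect_equal(delta_fbm(0.6), 0.6)
  expect_equal(delta_fbm(0.9), 0.9)
})

test_that("dea objects carry a complete, consistent fit summary", {
  set.seed(43)
  f <- dea(rnorm(5e4))
  expect_s3_class(f, "dea")
  expect_named(coef(f), c("A", "delta"))
  expect_equal(unname(coef(f)["delta"]), f$delta)
  expect_equal(predict(f, l = exp(1)), f$A + f$delta)
  expect_equal(length(residuals(f)), nrow(f$curve))
  expect_lt(summary(f)$rms, 0.1)
  expect_output(print(f), "delta")
  expect_output(print(summary(f)), "residuals")
  # plot method draws without error
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
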