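#' Fit the entropy scaling law S(l) = A + delta * log(l)
#'
#' Ordinary least squares of the entropy curve against log window length,
#' restricted to `[l_min, l_max]`. The slope delta is the scaling index of
#' the diffusion process; the intercept A absorbs the histogram bin width
#' and the amplitude of the increments.
#'
#' @param curve data.frame with columns `l` and `S`, e.g. from
#'   [dea_curve()].
#' @param l_min,l_max fit range; defaults cover the whole curve.
#' @return a `"dea_fit"` list: `delta` (slope), `A` (intercept, nats),
#'   `se` (standard error of the slope), `fit_range`, `n_points`.
#' @examples
#' curve <- data.frame(l = c(10, 100, 1000), S = 1 + 0.75 * log(c(10, 100, 1000)))
#' fit_delta(curve)$delta   # 0.75
#' @export
fit_delta <- function(curve, l_min = NULL, l_max = NULL) {
  if (!is.data.frame(curve) || !all(c("l", "S") %in% names(curve)))
    stop("'curve' must be a data.frame with columns 'l' and 'S'",
         call. = FALSE)
  if (is.null(l_min)) l_min <- min(curve$l)
  if (is.null(l_max)) l_max <- max(curve$l)
  if (l_min >= l_max) stop("'l_min' must be < 'l_max'", call. = FALSE)
  keep <- curve$l >= l_min & curve$l <= l_max & is.finite(curve$S)
  if (sum(keep) < 3L)
    stop("need at least 3 curve points inside the fit range", call. = FALSE)
  fit <- stats::lm(S ~ log(l), data = curve[keep, ])
  cf <- stats::coef(fit)
  # slope standard error computed directly (an exact synthetic line has
  # zero residuals, where summary.lm would warn)
  lx <- log(curve$l[keep])
  s2 <- sum(stats::residuals(fit)^2) / (sum(keep) - 2)
  se <- sqrt(s2 / sum((lx - mean(lx))^2))
  structure(list(delta = unname(cf[2]), A = unname(cf[1]), se = unname(se),
                 fit_range = c(l_min, l_max), n_points = sum(keep)),
            class = "dea_fit")
}

#' @export
print.dea_fit <- function(x, ...) {
  cat(sprintf("S(l) = A + delta log l:  delta = %.4f (se %.4f), A = %.4f\n",
              x$delta, x$se, x$A))
  cat(sprintf("fit over l in [%g, %g] (%d points)\n",
              x$fit_range[1], x$fit_range[2], x$n_points))
  invisible(x)
}

#' Theoretical scaling index of pure crucial events
#'
#' The DEA scaling of the one-sided event-count walker driven by renewal
#' events with IPL waiting-time index mu:
#' \deqn{\delta = \mu - 1 \quad (1 < \mu \le 2), \qquad
#'       \delta = 1/(\mu - 1) \quad (2 < \mu < 3),}
#' continuous with maximum 1 at mu = 2. For mu >= 3 the waiting times have
#' finite variance and diffusion is ordinary (delta = 0.5); that value is
#' returned only when `allow_ordinary = TRUE`, otherwise mu outside (1, 3)
#' is an error.
#'
#' @param mu IPL waiting-time index.
#' @param allow_ordinary return 0.5 for mu >= 3 instead of erroring.
#' @return scaling index delta.
#' @examples
#' delta_crucial(2.5)   # 2/3
#' delta_crucial(1.8)   # 0.8
#' @export
delta_crucial <- function(mu, allow_ordinary = FALSE) {
  stop_if_not_scalar(mu, "mu")
  if (mu >= 3 && allow_ordinary) return(0.5)
  if (mu <= 1 || mu >= 3)
    stop("'mu' must lie in (1, 3); mu >= 3 is ordinary scaling ",
         "(use allow_ordinary = TRUE for 0.5)", call. = FALSE)
  if (mu <= 2) mu - 1 else 1 / (mu - 1)
}

#' Theoretical scaling index of pure fractional Brownian motion
#'
#' DEA without stripes on fBm recovers the Hurst exponent: delta = H.
#'
#' @param H Hurst exponent in (0, 1).
#' @return scaling index delta = H.
#' @export
delta_fbm <- function(H) {
  check_hurst(H)
  H
}

#' Scaling index of the fractional diffusion equation with time-dependent
#' diffusivity
#'
#' For diffusion governed jointly by a Caputo fractional time derivative of
#' order alpha (crucial events with mu = 1 + alpha) and a diffusion
#' coefficient growing as t^(2H - 1) (fBm memory), the second-moment scaling
#' index is
#' \deqn{\delta = (2H - 1 + \alpha) / 2.}
#' At alpha = 1 this reduces to the fBm value H; at H = 0.5 it reduces to
#' alpha/2, the symmetric-step CTRW scaling (mu - 1)/2.
#'
#' @param H Hurst exponent in (0, 1).
#' @param alpha Caputo order in (0, 1]; equals mu - 1 for 1 < mu < 2.
#' @return scaling index delta.
#' @export
delta_fde <- function(H, alpha) {
  check_hurst(H)
  stop_if_not_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  (2 * H - 1 + alpha) / 2
}
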