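#' Autocovariance of fractional Gaussian noise
#'
#' Closed-form autocovariance of unit-variance fGn with Hurst exponent H:
#' \deqn{\gamma(k) = \tfrac12\left(|k+1|^{2H} - 2|k|^{2H} +
#'   |k-1|^{2H}\right).}
#' At H = 0.5 this is 0 for all k >= 1 (white noise); for H > 0.5 it decays
#' as \eqn{H(2H-1) k^{2H-2}}, i.e. as \eqn{k^{-\eta}} with \eqn{\eta = 2-2H}.
#'
#' @param k vector of integer lags (>= 0).
#' @param H Hurst exponent in (0, 1).
#' @return numeric vector of autocovariances.
#' @export
fgn_acvf <- function(k, H) {
  check_hurst(H)
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

check_hurst <- function(H) {
  stop_if_not_scalar(H, "H")
  if (H <= 0 || H >= 1) stop("'H' must lie in (0, 1)", call. = FALSE)
  invisible(NULL)
}

#' Synthesize fractional Gaussian noise
#'
#' Generates a stationary, zero-mean, unit-variance Gaussian series whose
#' cumulative sum is fractional Brownian motion, i.e. whose partial-sum
#' variance grows as \eqn{n^{2H}}.
#'
#' Three methods are available:
#' \describe{
#'   \item{`"circulant"`}{(default) exact circulant embedding (Davies-Harte):
#'     the fGn autocovariance out to lag m is embedded in a circulant matrix
#'     whose eigenvalues are obtained by FFT; the output has exactly the
#'     target covariance at O(n log n) cost. For fGn the embedding is
#'     nonnegative definite for all H in (0, 1); should a (numerically)
#'     negative eigenvalue ever appear it is clamped to zero with a warning
#'     and the result is approximate.}
#'   \item{`"mvn"`}{truncated Mandelbrot-van Ness moving average: the fBm
#'     kernel increments \eqn{a_0 = 1}, \eqn{a_i = (i+1)^{H-1/2} -
#'     i^{H-1/2}} weight an i.i.d. Gaussian stream over a window of `K` past
#'     innovations, and the result is rescaled to unit variance. Approximate
#'     (the kernel is truncated), O(nK); kept as an independently coded
#'     cross-check of the circulant generator.}
#'   \item{`"spectral"`}{superposition of cosines with random phases and
#'     frequencies drawn from a power-law spectral density; see
#'     [fgn_spectral()].}
#' }
#'
#' @param n series length in ticks.
#' @param H Hurst exponent in (0, 1). H = 0.5 gives i.i.d. standard normals.
#' @param method one of `"circulant"`, `"mvn"`, `"spectral"`.
#' @param seed optional integer seed for a local RNG stream.
#' @param ... further arguments passed to the method (`K` for `"mvn"`,
#'   `n_modes` and `band` for `"spectral"`).
#' @return numeric vector of length n.
#' @examples
#' x <- fgn(4096, H = 0.75, seed = 1)
#' acf(x, lag.max = 1, plot = FALSE)   # lag-1 ~ 2^(2*0.75 - 1) - 1 = 0.414
#' @export
fgn <- function(n, H, method = c("circulant", "mvn", "spectral"),
                seed = NULL, ...) {
  method <- match.arg(method)
  check_hurst(H)
  stop_if_not_scalar(n, "n")
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  switch(method,
         circulant = fgn_circulant(n, H, seed = seed),
         mvn       = fgn_mvn(n, H, seed = seed, ...),
         spectral  = fgn_spectral(n, H, seed = seed, ...))
}

fgn_circulant <- function(n, H, seed = NULL) {
  m <- 2^ceiling(log2(max(n, 2)))
  g <- c(fgn_acvf(0:m, H), fgn_acvf((m - 1):1, H))   # circulant first row, 2m
  lam <- Re(stats::fft(g))
  if (min(lam) < -1e-8 * max(lam))
    warning("circulant embedding not nonnegative definite; ",
            "negative eigenvalues clamped to zero (result approximate)")
  lam <- pmax(lam, 0)
  with_seed(seed, {
    z <- complex(real = stats::rnorm(2 * m), imaginary = stats::rnorm(2 * m))
    Re(stats::fft(sqrt(lam) * z))[seq_len(n)] / sqrt(2 * m)
  })
}

fgn_mvn <- function(n, H, K = 2000L, seed = NULL) {
  stop_if_not_scalar(K, "K")
  i <- seq_len(K)
  a <- c(1, (i + 1)^(H - 0.5) - i^(H - 0.5))          # truncated MvN kernel
  a <- a / sqrt(sum(a^2))                             # unit marginal variance
  with_seed(seed, {
    eps <- stats::rnorm(n + K)
    as.numeric(stats::filter(eps, a, method = "convolution",
                             sides = 1))[(K + 1):(n + K)]
  })
}

#' Spectral (Weiss-type) generator of long-memory Gaussian noise
#'
#' Builds the noise as a superposition of `n_modes` cosines,
#' \deqn{\xi(t) = \sqrt{2 / n_{modes}} \sum_k \cos(\omega_k t + \phi_k),}
#' with phases uniform on \eqn{[0, 2\pi)} and frequencies drawn from the
#' power-law spectral density \eqn{\rho(\omega) \propto \omega^{\eta - 1}}
#' on the band `band`, where \eqn{\eta = 2 - 2H}. The ensemble
#' autocorrelation then decays as \eqn{t^{-\eta}} within the band-limited
#' regime, matching the fGn correlation tail for Hurst exponent
#' \eqn{H = 1 - \eta/2}. The series has unit variance in expectation.
#'
#' @param n series length in ticks.
#' @param H Hurst exponent in (0, 1); the spectral exponent is eta = 2 - 2H.
#' @param n_modes number of cosine modes; 0 returns the zero series (a
#'   message is emitted).
#' @param band frequency band (low, high) from which modes are drawn;
#'   defaults to `c(2*pi/n, pi)`, the resolvable scales of the series.
#' @param seed optional integer seed for a local RNG stream.
#' @return numeric vector of length n.
#' @export
fgn_spectral <- function(n, H, n_modes = 1000L, band = c(2 * pi / n, pi),
                         seed = NULL) {
  check_hurst(H)
  stop_if_not_scalar(n, "n")
  stop_if_not_scalar(n_modes, "n_modes")
  if (n_modes < 0) stop("'n_modes' must be >= 0", call. = FALSE)
  if (n_modes == 0) {
    message("fgn_spectral: n_modes = 0, returning the zero series")
    return(numeric(n))
  }
  eta <- 2 - 2 * H
  if (band[1] <= 0 || band[2] <= band[1])
    stop("'band' must satisfy 0 < low < high", call. = FALSE)
  with_seed(seed, {
    u <- stats::runif(n_modes)
    # inverse CDF of density ~ omega^(eta-1) on [w1, w2]
    w <- (band[1]^eta + u * (band[2]^eta - band[1]^eta))^(1 / eta)
    phi <- stats::runif(n_modes, 0, 2 * pi)
    t <- seq_len(n)
    x <- numeric(n)
    for (k in seq_len(n_modes)) x <- x + cos(w[k] * t + phi[k])
    sqrt(2 / n_modes) * x
  })
}
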