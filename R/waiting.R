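#' Hyperbolic (inverse-power-law) waiting-time distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the waiting-time law of crucial events,
#' \deqn{\psi(\tau) = (\mu - 1)\, T^{\mu - 1} / (\tau + T)^{\mu}, \quad
#'       \tau \ge 0,}
#' whose survival function is \eqn{\Psi(\tau) = (T / (T + \tau))^{\mu - 1}}.
#' The tail is an inverse power law with index \eqn{\mu}; the mean is
#' \eqn{T / (\mu - 2)} for \eqn{\mu > 2} and diverges for \eqn{\mu \le 2}.
#'
#' Sampling inverts the survival function: with \eqn{u} uniform on (0, 1),
#' \eqn{\tau = T (u^{-1/(\mu - 1)} - 1)}.
#'
#' @param x,q vector of waiting times (>= 0).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu IPL index; must exceed 1 for the density to be normalizable.
#'   The crucial-event regime of interest is 1 < mu < 3.
#' @param T waiting-time scale parameter, in ticks (> 0).
#' @param seed optional integer; seeds a local RNG stream (see Details in
#'   [crucial_times()]).
#' @return numeric vector.
#' @examples
#' qcrucial(0.5, mu = 2, T = 1)    # median = 1
#' mean(rcrucial(1e4, mu = 2.5))   # ~ T / (mu - 2) = 2
#' @name crucial_waiting
NULL

check_waiting_params <- function(mu, T) {
  stop_if_not_scalar(mu, "mu")
  stop_if_not_scalar(T, "T")
  if (mu <= 1) stop("'mu' must be > 1 (density not normalizable otherwise)",
                    call. = FALSE)
  if (T <= 0) stop("'T' must be > 0", call. = FALSE)
  invisible(NULL)
}

#' @rdname crucial_waiting
#' @export
dcrucial <- function(x, mu, T = 1) {
  check_waiting_params(mu, T)
  out <- numeric(length(x))
  ok <- x >= 0
  out[ok] <- (mu - 1) * T^(mu - 1) / (x[ok] + T)^mu
  out
}

#' @rdname crucial_waiting
#' @export
pcrucial <- function(q, mu, T = 1) {
  check_waiting_params(mu, T)
  out <- numeric(length(q))
  ok <- q >= 0
  out[ok] <- 1 - (T / (T + q[ok]))^(mu - 1)
  out
}

#' @rdname crucial_waiting
#' @export
qcrucial <- function(p, mu, T = 1) {
  check_waiting_params(mu, T)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("'p' must lie in [0, 1]", call. = FALSE)
  T * ((1 - p)^(-1 / (mu - 1)) - 1)
}

#' @rdname crucial_waiting
#' @export
rcrucial <- function(n, mu, T = 1, seed = NULL) {
  check_waiting_params(mu, T)
  with_seed(seed, T * (stats::runif(n)^(-1 / (mu - 1)) - 1))
}

#' Generate a crucial-event train
#'
#' Simulates a renewal process whose waiting times follow the hyperbolic PDF
#' of [dcrucial()] and returns the event times mapped onto an integer tick
#' grid. Waiting times are accumulated in continuous time starting at 0 (the
#' first event is drawn from the same law, with no aging preparation); the
#' event occupying continuous time t is assigned tick `floor(t) + 1`. A tick
#' hosts at most one event, so same-tick collisions (waiting times shorter
#' than one tick) are merged; flooring and merging leave the
#' inverse-power-law tail untouched.
#'
#' @param length total number of ticks in the series (>= 1).
#' @param mu IPL index, > 1.
#' @param T waiting-time scale in ticks, > 0.
#' @param seed optional integer seed for a local RNG stream; the caller's
#'   RNG state is restored on exit. Identical seeds give identical trains.
#' @return strictly increasing integer vector of event ticks in
#'   `[1, length]`; possibly empty.
#' @examples
#' crucial_times(1000, mu = 2.5, T = 1, seed = 1)
#' @export
crucial_times <- function(length, mu, T = 1, seed = NULL) {
  check_waiting_params(mu, T)
  stop_if_not_scalar(length, "length")
  if (length < 1) stop("'length' must be >= 1", call. = FALSE)
  with_seed(seed, {
    times <- numeric(0)
    total <- 0
    # draw in chunks until the cumulative time leaves the observation window
    chunk <- max(1024L, if (mu > 2) ceiling(1.2 * length / (T / (mu - 2)))
                        else 1024L)
    while (total <= length) {
      w <- rcrucial(chunk, mu, T)
      times <- c(times, total + cumsum(w))
      total <- times[base::length(times)]
    }
    # a tick can host at most one event: drop same-tick collisions
    ticks <- unique(floor(times[times <= length]) + 1)
    as.integer(ticks[ticks <= length])
  })
}
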