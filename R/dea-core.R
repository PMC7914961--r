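#' Diffusion trajectory of a signal
#'
#' Converts a fluctuation series xi(t) into the diffusion trajectory
#' X(t) = sum of xi up to and including tick t (discrete cumulative sum),
#' the object DEA operates on.
#'
#' @param x numeric fluctuation series.
#' @return numeric vector, same length.
#' @export
diffusion_trajectory <- function(x) {
  if (length(x) == 0L) stop("empty series", call. = FALSE)
  if (!all(is.finite(x))) stop("series contains non-finite values",
                               call. = FALSE)
  cumsum(as.numeric(x))
}

#' Mobile-window displacements
#'
#' Slides a window of length l along the trajectory and records the
#' displacement Y(l, t) = X(t + l) - X(t) at every position (stride 1 by
#' default), treating each window as a walker that starts at the origin.
#'
#' @param X numeric diffusion trajectory.
#' @param l window length in ticks, `1 <= l < length(X)`.
#' @param stride step between window origins (>= 1); 1 uses every position.
#' @return numeric vector of `floor((length(X) - l - 1)/stride) + 1`
#'   displacements (`length(X) - l` at stride 1).
#' @export
window_displacements <- function(X, l, stride = 1L) {
  n <- length(X)
  stop_if_not_scalar(l, "l")
  if (l < 1 || l >= n)
    stop("'l' must satisfy 1 <= l < length(X)", call. = FALSE)
  idx <- seq.int(1L, n - l, by = stride)
  X[idx + l] - X[idx]
}

#' Shannon entropy of a displacement ensemble
#'
#' Histograms the displacements with a fixed bin width anchored at 0 (bin i
#' covers [i*w, (i+1)*w)) and returns the Shannon entropy
#' S = -sum p_i log p_i over occupied bins, in nats. Empty bins contribute
#' nothing. For an entropy *curve* the same bin width must be used at every
#' window length so the additive log(width) offset cancels in the slope.
#'
#' @param y numeric displacements (>= 2 values).
#' @param bin_width histogram bin width (> 0), in the units of y.
#' @return entropy in nats (single number, >= 0).
#' @examples
#' entropy_hist(c(0.1, 1.1, 2.1, 3.1), 1)   # four singleton bins: log(4)
#' @export
entropy_hist <- function(y, bin_width) {
  if (length(y) < 2L) stop("need at least 2 displacements", call. = FALSE)
  stop_if_not_scalar(bin_width, "bin_width")
  if (bin_width <= 0) stop("'bin_width' must be > 0", call. = FALSE)
  idx <- floor(y / bin_width)
  rng <- range(idx)
  if (rng[2] - rng[1] > 1e8)
    stop("bin width far too small for the displacement range", call. = FALSE)
  counts <- tabulate(idx - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  p <- counts[counts > 0L] / length(y)
  -sum(p * log(p))
}

#' Log-spaced window-length grid
#'
#' Default analysis grid: `n_points` log-spaced unique integers between
#' `l_min` and `l_max`. The defaults (10 to length/100) avoid the
#' small-window discreteness of the histogram and the large-window regime
#' where too few mobile windows remain to populate it.
#'
#' @param n series length in ticks.
#' @param n_points number of grid points requested (deduplication may return
#'   fewer).
#' @param l_min,l_max grid limits in ticks.
#' @return increasing integer vector.
#' @export
l_grid <- function(n, n_points = 25L, l_min = 10, l_max = n / 100) {
  if (l_max <= l_min)
    stop("series too short for the default window grid; supply 'l'",
         call. = FALSE)
  unique(round(exp(seq(log(l_min), log(l_max), length.out = n_points))))
}

#' Diffusion-entropy curve
#'
#' Computes S(l) = Shannon entropy of the mobile-window displacement
#' histogram at each window length of the grid, with one fixed bin width
#' across the whole curve.
#'
#' If `bin_width` is `NULL` it is set by Scott's rule evaluated at the
#' *smallest* window length of the grid, `3.49 * sd(Y(l_min)) * m^(-1/3)`,
#' and held fixed: anchoring the width at the narrowest displacement
#' distribution keeps every histogram on the curve resolved (larger windows
#' simply occupy more bins), while the constant width makes the log(width)
#' offset cancel in the slope.
#'
#' @param X numeric diffusion trajectory.
#' @param l increasing vector of window lengths; default [l_grid()].
#' @param bin_width fixed histogram bin width; `NULL` for Scott's rule at
#'   the smallest l (use 1 for integer-valued walkers).
#' @param stride stride between window origins.
#' @return data.frame with columns `l` and `S` (nats) and attribute
#'   `"bin_width"`.
#' @export
dea_curve <- function(X, l = NULL, bin_width = NULL, stride = 1L) {
  n <- length(X)
  if (is.null(l)) l <- l_grid(n)
  l <- as.numeric(l)
  if (any(diff(l) <= 0)) stop("'l' must be strictly increasing",
                              call. = FALSE)
  if (l[1] < 1 || l[length(l)] >= n)
    stop("'l' must lie within [1, length(X))", call. = FALSE)
  if (is.null(bin_width)) {
    y0 <- window_displacements(X, l[1], stride)
    bin_width <- 3.49 * stats::sd(y0) * length(y0)^(-1 / 3)
    if (!is.finite(bin_width) || bin_width <= 0)
      stop("cannot choose a bin width: degenerate displacements at l = ",
           l[1], "; supply 'bin_width'", call. = FALSE)
  }
  S <- vapply(l, function(li)
    entropy_hist(window_displacements(X, li, stride), bin_width), 0)
  structure(data.frame(l = l, S = S), bin_width = bin_width)
}
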