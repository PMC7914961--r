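#' Assign amplitude stripes
#'
#' Discretizes a signal into equal-width horizontal stripes:
#' `index[t] = floor((x[t] - origin) / width)`. Stripes are the event
#' detector of MDEA: a change of stripe index between consecutive ticks is
#' counted as an event.
#'
#' @param x numeric signal.
#' @param width stripe width in signal units (> 0). Default: half the
#'   sample standard deviation, which keeps a handful of stripes occupied
#'   for a roughly unit-scale signal; for dichotomous +/-1 signals use 1.
#' @param origin stripe boundary anchor in signal units.
#' @return integer vector of stripe indices, with the width and origin used
#'   attached as attributes.
#' @export
assign_stripes <- function(x, width = NULL, origin = 0) {
  if (is.null(width)) {
    width <- stats::sd(x) / 2
    if (!is.finite(width) || width <= 0)
      stop("cannot choose a stripe width for a constant signal; ",
           "supply 'width'", call. = FALSE)
  }
  stop_if_not_scalar(width, "width")
  if (width <= 0) stop("'width' must be > 0", call. = FALSE)
  structure(as.integer(floor((x - origin) / width)),
            width = width, origin = origin)
}

#' Detect stripe-crossing events
#'
#' Flags tick t whenever the stripe index differs from that at t - 1; the
#' first tick is never an event. On a coin-toss-filled crucial-event series
#' with stripe width 1 the flags coincide with the crucial events at which
#' the coin changed sign, so the flagged process keeps the inverse-power-law
#' waiting-time tail.
#'
#' @param indices integer stripe indices per tick, from [assign_stripes()].
#' @return integer 0/1 vector of the same length; `[1] == 0`.
#' @export
stripe_events <- function(indices) {
  if (length(indices) == 0L) stop("empty index vector", call. = FALSE)
  c(0L, as.integer(diff(as.numeric(indices)) != 0))
}

#' Event-count walker
#'
#' Builds the one-directional diffusion trajectory of MDEA: the walker makes
#' a forward step of constant length 1 at every event and never steps back,
#' so X(t) is the number of events up to and including tick t. The one-sided
#' step rule is what yields delta = mu - 1 for 1 < mu < 2 (rather than
#' (mu - 1)/2 for symmetric +/- steps).
#'
#' @param flags 0/1 event indicator per tick, from [stripe_events()].
#' @return numeric non-decreasing trajectory of the same length.
#' @export
event_walker <- function(flags) {
  if (length(flags) == 0L) stop("empty event indicator", call. = FALSE)
  if (any(!flags %in% c(0, 1)))
    stop("'flags' must be 0/1", call. = FALSE)
  cumsum(as.numeric(flags))
}
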