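#' Fill laminar regions between crucial events by fair coin toss
#'
#' Builds the dichotomous signal analyzed alongside a crucial-event train:
#' the series is piecewise constant, holding the value +W or -W throughout
#' each laminar region (the stretch before the first event, between
#' consecutive events, and after the last event), with an independent fair
#' coin deciding the sign of every region.
#'
#' @param events strictly increasing integer event ticks in `[1, length]`,
#'   e.g. from [crucial_times()]. Each event starts a new laminar region.
#' @param length total series length in ticks.
#' @param W amplitude (> 0); the signal takes values in {+W, -W}.
#' @param seed optional integer seed for a local RNG stream.
#' @return numeric vector of length `length`.
#' @export
laminar_fill <- function(events, length, W = 1, seed = NULL) {
  stop_if_not_scalar(length, "length")
  stop_if_not_scalar(W, "W")
  if (W <= 0) stop("'W' must be > 0", call. = FALSE)
  check_event_ticks(events, length)
  with_seed(seed, {
    signs <- sample(c(-W, W), base::length(events) + 1L, replace = TRUE)
    region <- findInterval(seq_len(length), events) + 1L
    signs[region]
  })
}

check_event_ticks <- function(events, length) {
  if (base::length(events) == 0L) return(invisible(NULL))
  if (any(diff(events) <= 0))
    stop("'events' must be strictly increasing", call. = FALSE)
  if (events[1] < 1 || events[base::length(events)] > length)
    stop("'events' must lie in [1, length]", call. = FALSE)
  invisible(NULL)
}

#' Subordinate an increment sequence to a crucial-event train
#'
#' Implements the clock-time embedding of an operational-time process: the
#' n-th increment is assigned to the clock tick of the n-th event, and the
#' series is zero at every non-event tick. This realizes the
#' continuous-time-random-walk prescription: a process unfolding in
#' operational (event-count) time n is observed in laboratory time t through
#' the renewal times t(n).
#'
#' @param increments numeric vector of operational-time values; must supply
#'   at least one value per event (consumed in order).
#' @param events strictly increasing integer event ticks in `[1, length]`.
#' @param length total series length in ticks.
#' @return numeric vector of length `length`.
#' @examples
#' subordinate(c(1.5, -2), events = c(2, 5), length = 6)
#' @export
subordinate <- function(increments, events, length) {
  stop_if_not_scalar(length, "length")
  check_event_ticks(events, length)
  if (base::length(events) > base::length(increments))
    stop("more events (", base::length(events), ") than increments (",
         base::length(increments), ")", call. = FALSE)
  x <- numeric(length)
  x[events] <- increments[seq_along(events)]
  x
}

#' Combined crucial-event + fractional-noise series
#'
#' Generates the surrogate for diffusion driven jointly by crucial events
#' and long-range Gaussian memory: fractional Gaussian noise with Hurst
#' exponent H is synthesized in operational time and subordinated to the
#' clock times of a renewal train with IPL index mu. Independent RNG
#' sub-streams are derived from `seed` for the waiting times and the
#' Gaussian draws, so either component can be varied alone.
#'
#' @param length series length in ticks.
#' @param mu IPL waiting-time index (> 1).
#' @param H Hurst exponent of the operational-time noise, in (0, 1).
#' @param T waiting-time scale in ticks.
#' @param seed optional master integer seed.
#' @param method fGn synthesis method, see [fgn()].
#' @return numeric vector of length `length` with attribute `"events"`
#'   holding the event ticks.
#' @export
combined_series <- function(length, mu, H, T = 1, seed = NULL,
                            method = "circulant") {
  ev <- crucial_times(length, mu, T, seed = sub_seed(seed, 1L))
  if (base::length(ev) == 0L) {
    x <- numeric(length)
  } else {
    xi <- fgn(base::length(ev), H, method = method,
              seed = sub_seed(seed, 2L))
    x <- subordinate(xi, ev, length)
  }
  attr(x, "events") <- ev
  x
}

#' Read / write a single-channel series as plain text
#'
#' The on-disk format is one numeric value per line, UTF-8, with optional
#' leading comment lines of the form `# key=value` carrying generation
#' parameters. A CSV file with a `value` column is also accepted on read.
#'
#' @param x numeric vector to write.
#' @param path file path.
#' @param params named list of parameters written as `# key=value` header
#'   lines.
#' @return `read_series()` returns the numeric vector with the parsed header
#'   in `attr(, "params")` (a named character vector); `write_series()`
#'   returns `path` invisibly.
#' @export
write_series <- function(x, path, params = list()) {
  hdr <- if (length(params))
    sprintf("# %s=%s", names(params), vapply(params, format, ""))
  else character(0)
  writeLines(c(hdr, sprintf("%.17g", as.numeric(x))), path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("empty series file: ", path, call. = FALSE)
  params <- character(0)
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", hdr)
    kv <- kv[grepl("=", kv)]
    params <- sub("^[^=]*=", "", kv)
    names(params) <- sub("=.*$", "", kv)
  }
  first <- body[1]
  if (grepl(",", first) ||
      is.na(suppressWarnings(as.numeric(first)))) {
    df <- utils::read.csv(text = paste(body, collapse = "\n"))
    if (!"value" %in% names(df))
      stop("CSV series file must have a 'value' column", call. = FALSE)
    vals <- as.numeric(df$value)
  } else {
    vals <- as.numeric(body)
  }
  if (anyNA(vals)) stop("non-numeric entries in series file", call. = FALSE)
  structure(vals, params = params)
}
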