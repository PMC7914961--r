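#' Write / read a flat key=value analysis report
#'
#' Serializes a fitted `"dea"` object as diffable `key=value` lines:
#' the fitted `delta`, `A` and `stderr`, the fit range, the bin and stripe
#' widths, the series length and event count, the tool version, plus any
#' extra parameters supplied (e.g. generator settings and the seed), so the
#' report echoes everything needed to reproduce it.
#'
#' @param fit a `"dea"` object from [dea()] or [mdea()].
#' @param path file path; `write_report()` writes, [read_report()] parses.
#' @param extra named list of additional key=value pairs to record.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a named character vector.
#' @export
write_report <- function(fit, path, extra = list()) {
  stopifnot(inherits(fit, "dea"))
  kv <- c(list(mode = if (fit$stripes) "mdea" else "dea",
               delta = fit$delta, A = fit$A, stderr = fit$se,
               fit_min = fit$fit_range[1], fit_max = fit$fit_range[2],
               n_points = fit$n_points, bin_width = fit$bin_width,
               stripe_width = fit$stripe_width, n_events = fit$n_events,
               length = fit$n,
               version = as.character(utils::packageVersion("mdea"))),
          extra)
  writeLines(sprintf("%s=%s", names(kv),
                     vapply(kv, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines)]
  structure(sub("^[^=]*=", "", lines),
            names = sub("=.*$", "", lines))
}

#' Write an entropy curve as two-column text
#'
#' One `l S` pair per line, ready for replotting.
#'
#' @param curve data.frame with columns `l` and `S` (a `"dea"` object's
#'   `$curve` works directly).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(curve[, c("l", "S")], path, row.names = FALSE,
                     col.names = c("l", "S"), quote = FALSE)
  invisible(path)
}

#' Deterministic fixture series for tests and examples
#'
#' Generates the small series the unit tests run on — a 1e4-tick
#' crucial-event train with mu = 2.5 filled by coin toss, a short fGn
#' series with H = 0.6, and a short combined (subordinated) series — and
#' writes them under `dir` with full parameter headers. Regenerates
#' identically for the same seed.
#'
#' @param seed master integer seed.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(crucial = file.path(dir, "crucial_mu2.5.txt"),
             fgn = file.path(dir, "fgn_H0.6.txt"),
             combined = file.path(dir, "combined_mu2.5_H0.9.txt"))
  n <- 10000L
  ev <- crucial_times(n, mu = 2.5, T = 1, seed = sub_seed(seed, 11L))
  x <- laminar_fill(ev, n, W = 1, seed = sub_seed(seed, 12L))
  write_series(x, paths["crucial"],
               params = list(kind = "crucial", mu = 2.5, T = 1, length = n,
                             W = 1, seed = seed))
  g <- fgn(4096L, H = 0.6, seed = sub_seed(seed, 13L))
  write_series(g, paths["fgn"],
               params = list(kind = "fbm", H = 0.6, length = 4096L,
                             seed = seed))
  cmb <- combined_series(n, mu = 2.5, H = 0.9, T = 1,
                         seed = sub_seed(seed, 14L))
  write_series(cmb, paths["combined"],
               params = list(kind = "combined", mu = 2.5, H = 0.9, T = 1,
                             length = n, seed = seed))
  invisible(paths)
}
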