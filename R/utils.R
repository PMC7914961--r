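# Seed plumbing: every generator takes `seed = NULL`. NULL means "use the
# RNG stream as-is"; an integer seeds a local stream and restores the caller's
# .Random.seed on exit, so fixed-seed calls are bit-reproducible without
# clobbering the session RNG.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive an independent sub-stream seed from a master seed (kept < 2^31 so it
# stays a valid R integer). Component k of the same master never collides
# with component k of master + 1 in practice because of the large multiplier.
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + k * 7919) %% 2147483647L
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
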