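# Shared helpers: small deterministic inputs built in code.

# log-log slope of y against x by OLS, for tail/variance scaling checks
loglog_slope <- function(x, y) {
  keep <- is.finite(log(y))
  unname(coef(stats::lm(log(y[keep]) ~ log(x[keep])))[2])
}

# sample autocovariance at one lag (biased, mean assumed 0 for generators
# that are zero-mean by construction)
acvf0 <- function(x, k) {
  n <- length(x)
  mean(x[seq_len(n - k)] * x[seq_len(n - k) + k])
}
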