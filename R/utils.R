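# Internal numeric helpers shared across modules.

# log(exp(a) - exp(b)) for a >= b, stable for a ~ b and very negative values.
log_diff_exp <- function(a, b) {
  out <- rep(-Inf, length(a))
  ok <- is.finite(a) & a > b
  d <- b[ok] - a[ok]
  out[ok] <- a[ok] + log1p(-exp(d))
  out
}

log_sum_exp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic child seeds derived from one master seed, so independent
# stages of a simulation never share a random stream. Kept below 2^31.
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + stream * 7919L
}

# log-sum-exp of `terms` grouped by integer `g` in 1..n, vectorized via a
# padded matrix (groups are small and contiguous in all callers)
grouped_lse <- function(terms, g, n) {
  cnt <- tabulate(g, n)
  mat <- matrix(-Inf, n, max(cnt))
  pos <- sequence(cnt)
  mat[cbind(g, pos)] <- terms
  mx <- apply(mat, 1, max)
  ok <- is.finite(mx)
  out <- mx
  out[ok] <- mx[ok] + log(rowSums(exp(mat[ok, , drop = FALSE] - mx[ok])))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
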