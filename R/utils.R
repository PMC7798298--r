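# internal numerical helpers

# row maxima without apply(); column count is small (K or L)
row_max <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx
}

# numerically safe log-sum-exp over the last margin of a matrix (rows kept)
logsumexp_rows <- function(m) {
  mx <- row_max(m)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  # rows that are all -Inf stay -Inf instead of NaN
  out[bad] <- mx[bad]
  out
}

logsumexp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

# row-wise softmax from log weights
softmax_rows <- function(m) {
  e <- exp(m - row_max(m))
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parameter floors keeping logs finite (see methods vignette)
.ALPHA_MIN <- 1e-6
.ALPHA_MAX <- 1e6
.Q_FLOOR <- 1e-10

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

# derive a child seed from a base seed, kept inside 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(i) * 12347L) %% 2147483629)
}
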