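#' Posterior-mean imputation of observed zeros
#'
#' Non-zero counts are kept as observed.  An observed zero is replaced by
#' its posterior mean under the fitted model: with probability
#' \eqn{p(\mathrm{dropout} \mid k, x=0)} the zero is a detection failure and
#' the best estimate is the expressed-component mean
#' \eqn{s_c \sum_{l>0} p(l \mid k, x, \mathrm{expressed})\,
#' \alpha_{g,k,l}/\beta_{g,k,l}}; with the complementary probability the
#' zero is real and contributes 0.  Averaging over the cell's cluster
#' posterior \eqn{p(k \mid x_c)} gives the imputed value.  Intended for
#' visualization only; clustering and DEG testing operate on the raw
#' counts.
#'
#' @param counts `count_matrix` or coercible integer matrix.
#' @param params fitted [zinb_params()] (or a `zinb_fit`).
#' @param scalers per-cell scalers (defaults to the fit's, else unit).
#' @return object of class `zinb_imputed`: `values` (numeric C x G matrix)
#'   and `mask` (logical C x G, `TRUE` where a value was imputed).
#' @examples
#' # worked example: posterior dropout probability 0.2, NB mean 5 -> 1
#' nb0 <- (1 / 2)^5                      # P(NB(5,1) draw = 0), s = 1
#' q0 <- 0.2 * nb0 / (0.8 + 0.2 * nb0)   # prior weight giving posterior 0.2
#' p <- zinb_params(1, c(q0, 1 - q0), 5, 1)
#' impute_zeros(matrix(0L, 1, 1), p)$values  # exactly 1
#' @export
impute_zeros <- function(counts, params, scalers = NULL) {
  if (inherits(params, "zinb_fit")) {
    if (is.null(scalers)) scalers <- params$scalers
    params <- params$params
  }
  counts <- as_count_matrix(counts)
  validate_params(params)
  X <- counts$counts
  if (ncol(X) != params$G) stop("gene dimension mismatch")
  C <- nrow(X); G <- ncol(X); K <- params$K
  s <- expand_scalers(scalers, C)
  es <- e_step(counts, params, scalers)
  values <- X
  mask <- X == 0 & matrix(TRUE, C, G)
  if (!params$dropout) {
    # no dropout component: every observed zero is a true zero
    return(structure(list(values = values, mask = mask & FALSE),
                     class = "zinb_imputed"))
  }
  l0 <- 1L
  # expressed-component posteriors at x = 0 do not depend on the cell except
  # through s; evaluate per (g, k) for each cell's scaler
  m_nb <- params$alpha / params$beta                     # G x K x n_nb
  for (g in seq_len(G)) {
    zc <- which(X[, g] == 0)
    if (length(zc) == 0) next
    acc <- numeric(length(zc))
    for (k in seq_len(K)) {
      p0 <- es$comp_post[zc, g, k, 1]                    # posterior dropout prob
      # p(l | k, x=0, expressed): renormalize prior-weighted NB masses at 0
      lw <- vapply(seq_len(params$n_nb), function(j)
        log(params$q[g, k, l0 + j]) +
          nb_log_pmf(rep(0, length(zc)), params$alpha[g, k, j],
                     params$beta[g, k, j], s[zc]),
        numeric(length(zc)))
      lw <- matrix(lw, nrow = length(zc))
      expressed_post <- softmax_rows(lw)                  # n_zc x n_nb
      mean_expressed <- as.numeric(expressed_post %*% m_nb[g, k, ])
      acc <- acc + es$gamma[zc, k] * p0 * mean_expressed
    }
    values[zc, g] <- s[zc] * acc
  }
  structure(list(values = values, mask = mask), class = "zinb_imputed")
}

#' @export
print.zinb_imputed <- function(x, ...) {
  cat(sprintf("zinb_imputed: %d x %d matrix, %d value(s) imputed\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}
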