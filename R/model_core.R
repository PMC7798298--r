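#' Log PMF of the Gamma-Poisson (negative binomial) component
#'
#' Marginalizing a Poisson intensity \eqn{\lambda \sim
#' \mathrm{Gamma}(\alpha, \beta)} out of \eqn{x \sim
#' \mathrm{Poisson}(s\lambda)} gives the negative binomial
#' \deqn{\log p(x) = \log\Gamma(x+\alpha) - \log\Gamma(\alpha) - \log x! +
#'   \alpha \log\frac{\beta}{\beta+s} + x \log\frac{s}{\beta+s}.}
#' All arguments recycle to a common length.
#'
#' @param x non-negative integer count(s).
#' @param alpha,beta positive Gamma shape and rate.
#' @param s positive cell scaler.
#' @return log probability mass, same length as the recycled arguments.
#' @examples
#' nb_log_pmf(0, 1, 1, 1)  # log(1/2): geometric special case
#' @export
nb_log_pmf <- function(x, alpha, beta, s = 1) {
  if (!is_count_vector(x)) stop("x must be non-negative integer counts")
  stopifnot(all(alpha > 0), all(beta > 0), all(s > 0))
  lgamma(x + alpha) - lgamma(alpha) - lgamma(x + 1) +
    alpha * log(beta / (beta + s)) + x * log(s / (beta + s))
}

# per-component log terms log(q_l) + log h_l(x) for one (g, k), vectorized
# over cells; returns C x L matrix.  h for the dropout component is the
# indicator 1{x == 0}.
component_log_terms <- function(x, g, k, params, s) {
  C <- length(x)
  out <- matrix(-Inf, C, params$L)
  l0 <- 0L
  if (params$dropout) {
    l0 <- 1L
    out[, 1] <- log(params$q[g, k, 1]) + ifelse(x == 0, 0, -Inf)
  }
  for (j in seq_len(params$n_nb)) {
    out[, l0 + j] <- log(params$q[g, k, l0 + j]) +
      nb_log_pmf(x, params$alpha[g, k, j], params$beta[g, k, j], s)
  }
  out
}

#' Log probability of one gene's count under one cluster
#'
#' Evaluates the per-gene mixture term
#' \eqn{\log[ q_{g,k,1} 1\{x=0\} + \sum_{l>1} q_{g,k,l}
#' \mathrm{NB}(x; \alpha_{g,k,l}, \beta_{g,k,l}, s) ]}
#' with a numerically safe log-sum over components.
#'
#' @param x_g non-negative integer count(s) for gene `g` (vectorized over
#'   cells).
#' @param g,k gene and cluster index (1-based).
#' @param params a [zinb_params()] object.
#' @param s positive cell scaler(s), recycled against `x_g`.
#' @return log probability, one value per element of `x_g`.
#' @export
gene_cluster_log_prob <- function(x_g, g, k, params, s = 1) {
  validate_params(params)
  if (g < 1 || g > params$G || k < 1 || k > params$K) stop("index out of bounds")
  if (!is_count_vector(x_g)) stop("x_g must be non-negative integer counts")
  s <- rep_len(s, length(x_g))
  logsumexp_rows(component_log_terms(x_g, g, k, params, s))
}

# full per-gene per-cluster log likelihood array: C x G x K
gene_loglik_array <- function(X, params, s) {
  C <- nrow(X); G <- ncol(X); K <- params$K
  logf <- array(NA_real_, c(C, G, K))
  for (k in seq_len(K)) {
    for (g in seq_len(G)) {
      logf[, g, k] <- logsumexp_rows(component_log_terms(X[, g], g, k, params, s))
    }
  }
  logf
}

#' Per-cell log likelihoods under the mixture
#'
#' For each cell, the log joint \eqn{\log \pi_k + \sum_g \log
#' f_{g,k}(x_{c,g})} per cluster and the total marginal log likelihood
#' (log-sum-exp over clusters).
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param params [zinb_params()].
#' @param scalers per-cell scalers (`NULL` = all 1; see
#'   [compute_cell_scalers()]).
#' @return list with `log_joint` (C x K), `total` (length-C vector).
#' @export
cell_log_likelihoods <- function(counts, params, scalers = NULL) {
  counts <- as_count_matrix(counts)
  validate_params(params)
  X <- counts$counts
  if (ncol(X) != params$G) stop("gene dimension mismatch")
  if (all(params$pi == 0)) stop("all mixture weights are zero")
  s <- expand_scalers(scalers, nrow(X))
  logf <- gene_loglik_array(X, params, s)
  per_gene_sum <- vapply(seq_len(params$K),
                         function(k) rowSums(logf[, , k, drop = FALSE]),
                         numeric(nrow(logf)))               # C x K
  per_gene_sum <- matrix(per_gene_sum, nrow(logf), params$K)
  log_joint <- sweep(per_gene_sum, 2, log(params$pi), "+")
  total <- logsumexp_rows(log_joint)
  if (any(!is.finite(total))) {
    c_bad <- which(!is.finite(total))[1]
    stop(sprintf("non-finite log likelihood for cell '%s'", counts$cell_ids[c_bad]))
  }
  list(log_joint = log_joint, total = total)
}

#' Total dataset log likelihood
#'
#' Sum of per-cell marginal log likelihoods; the quantity tracked for EM
#' convergence and penalized by AIC/BIC.
#'
#' @inheritParams cell_log_likelihoods
#' @return scalar log likelihood.
#' @export
dataset_log_likelihood <- function(counts, params, scalers = NULL) {
  sum(cell_log_likelihoods(counts, params, scalers)$total)
}

#' Closed-form zero-count probability
#'
#' Probability that gene `g` in cluster `k` yields a zero count:
#' \deqn{q_{g,k,0} + \sum_{l \ge 1} q_{g,k,l}
#'   \left(\frac{\beta_{g,k,l}}{\beta_{g,k,l}+s}\right)^{\alpha_{g,k,l}}.}
#'
#' @param g,k gene and cluster index.
#' @param params [zinb_params()].
#' @param s cell scaler(s); vectorized.
#' @return probability in `[0, 1]`, same length as `s`.
#' @export
zero_probability <- function(g, k, params, s = 1) {
  validate_params(params)
  if (g < 1 || g > params$G || k < 1 || k > params$K) stop("index out of bounds")
  p <- if (params$dropout) rep(params$q[g, k, 1], length(s)) else numeric(length(s))
  l0 <- as.integer(params$dropout)
  for (j in seq_len(params$n_nb)) {
    b <- params$beta[g, k, j]
    p <- p + params$q[g, k, l0 + j] * (b / (b + s))^params$alpha[g, k, j]
  }
  p
}
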