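#' Parameters of the generalized zero-inflated negative binomial mixture
#'
#' The model assumes that the observed count of gene \eqn{g} in a cell of
#' cell-type \eqn{k} follows a mixture over \eqn{L} components: component 1
#' is the dropout component (a point mass at zero, present whenever
#' \eqn{L \ge 2}), and each remaining component is a negative binomial
#' arising as a Gamma--Poisson mixture with shape \eqn{\alpha_{g,k,l}} and
#' rate \eqn{\beta_{g,k,l}}, scaled per cell by \eqn{s_c}.  With \eqn{L = 1}
#' there is no dropout term and the single component is a plain negative
#' binomial; \eqn{L = 2} is the zero-inflated negative binomial; \eqn{L = 3}
#' adds a second NB component.
#'
#' @param pi length-`K` probability vector of cell-type weights.
#' @param q `G x K x L` array of component weights; `q[g, k, ]` is a
#'   probability vector.  Component 1 is the dropout weight when `L >= 2`.
#' @param alpha,beta `G x K x n_nb` arrays of positive Gamma shape/rate
#'   parameters, where `n_nb = L - 1` if a dropout component is present and
#'   `1` otherwise.
#' @param dropout logical; whether component 1 of `q` is the dropout
#'   component.  Defaults to `TRUE` when `L >= 2`.
#' @return An object of class `zinb_params` with elements `K`, `G`, `L`,
#'   `n_nb`, `dropout`, `pi`, `q`, `alpha`, `beta`.
#' @export
zinb_params <- function(pi, q, alpha, beta, dropout = NULL) {
  pi <- as.numeric(pi)
  if (length(pi) == 1) {
    # single-cluster shorthand: bare vectors index components, not genes
    if (is.null(dim(q))) q <- array(q, c(1, 1, length(q)))
    if (is.null(dim(alpha))) alpha <- array(alpha, c(1, 1, length(alpha)))
    if (is.null(dim(beta))) beta <- array(beta, c(1, 1, length(beta)))
  }
  q <- as_3d_array(q)
  alpha <- as_3d_array(alpha)
  beta <- as_3d_array(beta)
  K <- length(pi)
  G <- dim(q)[1]
  L <- dim(q)[3]
  dropout <- dropout %||% (L >= 2)
  n_nb <- L - as.integer(dropout)
  if (n_nb < 1) stop("model needs at least one negative binomial component")
  p <- structure(list(K = K, G = G, L = L, n_nb = n_nb, dropout = dropout,
                      pi = pi, q = q, alpha = alpha, beta = beta),
                 class = "zinb_params")
  validate_params(p)
  p
}

as_3d_array <- function(x) {
  if (is.null(dim(x))) x <- array(x, c(length(x), 1, 1))
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  x
}

validate_params <- function(p, tol = 1e-8) {
  stopifnot(inherits(p, "zinb_params"))
  if (abs(sum(p$pi) - 1) > tol || any(p$pi < 0)) stop("pi must be a probability vector")
  if (!all(dim(p$q) == c(p$G, p$K, p$L))) stop("q has wrong dimensions")
  if (!all(dim(p$alpha) == c(p$G, p$K, p$n_nb))) stop("alpha has wrong dimensions")
  if (!all(dim(p$beta) == c(p$G, p$K, p$n_nb))) stop("beta has wrong dimensions")
  qs <- apply(p$q, c(1, 2), sum)
  if (any(abs(qs - 1) > tol) || any(p$q < 0)) stop("q[g,k,] must be probability vectors")
  if (any(p$alpha <= 0) || any(p$beta <= 0)) stop("alpha and beta must be positive")
  invisible(p)
}

#' @export
print.zinb_params <- function(x, ...) {
  cat(sprintf("zinb_params: K=%d clusters, G=%d genes, L=%d components (%s)\n",
              x$K, x$G, x$L,
              if (x$dropout) sprintf("dropout + %d NB", x$n_nb)
              else sprintf("%d NB, no dropout", x$n_nb)))
  cat("pi:", paste(signif(x$pi, 4), collapse = " "), "\n")
  invisible(x)
}

# index into alpha/beta for mixture component l (1-based, 1 = dropout if present)
nb_slot <- function(p, l) l - as.integer(p$dropout)

# clamp parameters to floors and renormalize simplexes; keeps logs finite
sanitize_params <- function(p) {
  p$alpha <- clip(p$alpha, .ALPHA_MIN, .ALPHA_MAX)
  p$beta <- clip(p$beta, .ALPHA_MIN, .ALPHA_MAX)
  p$q <- clip(p$q, .Q_FLOOR, 1)
  qs <- apply(p$q, c(1, 2), sum)
  p$q <- p$q / array(rep(qs, p$L), dim(p$q))
  p$pi <- clip(p$pi, .Q_FLOOR, 1)
  p$pi <- p$pi / sum(p$pi)
  p
}

# maximum relative change between two parameter sets (convergence check)
param_rel_change <- function(a, b, eps = 1e-8) {
  rel <- function(x, y) max(abs(x - y) / (abs(x) + eps))
  max(rel(a$pi, b$pi), rel(a$q, b$q), rel(a$alpha, b$alpha), rel(a$beta, b$beta))
}

# permute cluster labels together with their parameters
permute_clusters <- function(p, perm) {
  stopifnot(length(perm) == p$K)
  zinb_params(p$pi[perm], p$q[, perm, , drop = FALSE],
              p$alpha[, perm, , drop = FALSE], p$beta[, perm, , drop = FALSE],
              dropout = p$dropout)
}

#' Match fitted clusters to a reference parameter set
#'
#' Greedy matching of fitted clusters to reference clusters by the summed
#' absolute difference of NB means (\eqn{\alpha/\beta}) across genes; used to
#' resolve label switching before comparing parameter estimates.
#'
#' @param fitted,reference `zinb_params` with identical dimensions.
#' @return integer permutation `perm` such that fitted cluster `perm[k]`
#'   corresponds to reference cluster `k`.
#' @export
match_clusters <- function(fitted, reference) {
  stopifnot(fitted$K == reference$K)
  K <- fitted$K
  mean_f <- apply(fitted$alpha / fitted$beta, c(1, 2), sum)    # G x K
  mean_r <- apply(reference$alpha / reference$beta, c(1, 2), sum)
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    cost[i, j] <- sum(abs(mean_f[, i] - mean_r[, j]))
  perm <- integer(K)
  used <- rep(FALSE, K)
  # K is small (<= 10); greedy assignment in increasing cost order
  ord <- order(cost)
  for (idx in ord) {
    i <- (idx - 1) %% K + 1
    j <- (idx - 1) %/% K + 1
    if (!used[i] && perm[j] == 0) {
      perm[j] <- i
      used[i] <- TRUE
    }
  }
  perm
}
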