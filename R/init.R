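#' Initialization strategy for the EM fit
#'
#' The clustering method (`random`, `kmeans`, `spectral`) applied to a
#' transformed view of the counts produces hard starting labels, which are
#' converted into moment-based starting parameters.  The combinations
#' (kmeans | spectral) x (log1p, pca2, pca_25pct, pca_40pct) are the eight
#' standard starting conditions; see [default_init_strategies()].
#'
#' @param method one of `"random"`, `"kmeans"`, `"spectral"`.
#' @param transform one of `"log1p"`, `"pca2"`, `"pca_25pct"`,
#'   `"pca_40pct"`, `"none"`.
#' @param seed integer seed for the stochastic parts.
#' @return object of class `init_strategy`.
#' @export
init_strategy <- function(method = c("random", "kmeans", "spectral"),
                          transform = c("log1p", "pca2", "pca_25pct",
                                        "pca_40pct", "none"),
                          seed = 1L) {
  structure(list(method = match.arg(method), transform = match.arg(transform),
                 seed = as.integer(seed)),
            class = "init_strategy")
}

#' The eight standard initialization conditions
#'
#' K-means and spectral clustering, each on log1p counts, the first two PCs
#' of log1p counts, and the PCs explaining 25% or 40% of variance.
#'
#' @param seed base seed; each condition gets a derived child seed.
#' @return list of eight [init_strategy()] objects.
#' @export
default_init_strategies <- function(seed = 1L) {
  grid <- expand.grid(method = c("kmeans", "spectral"),
                      transform = c("log1p", "pca2", "pca_25pct", "pca_40pct"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    init_strategy(grid$method[i], grid$transform[i], seed = child_seed(seed, i)))
}

transform_counts <- function(X, transform) {
  Y <- log1p(X)
  switch(transform,
    none = X,
    log1p = Y,
    pca2 = pca_components(Y, n = 2),
    pca_25pct = pca_components(Y, var_frac = 0.25),
    pca_40pct = pca_components(Y, var_frac = 0.40))
}

pca_components <- function(Y, n = NULL, var_frac = NULL) {
  keep <- apply(Y, 2, stats::sd) > 0
  if (!any(keep)) return(Y[, 1, drop = FALSE] * 0)
  pc <- stats::prcomp(Y[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  if (is.null(n)) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n <- which(cum >= var_frac)[1]
  }
  n <- min(max(n, 1L), ncol(pc$x))
  pc$x[, seq_len(n), drop = FALSE]
}

# plain spectral clustering: Gaussian affinity, symmetric normalized
# Laplacian, k-means on the row-normalized top-K eigenvectors.  Dense
# O(C^2); callers with > spectral_max cells are redirected to k-means.
spectral_labels <- function(Y, K, seed, spectral_max = 3000L) {
  C <- nrow(Y)
  if (C > spectral_max) stop("too many cells for dense spectral clustering")
  d2 <- as.matrix(stats::dist(Y))^2
  sigma2 <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  A <- exp(-d2 / (2 * sigma2))
  diag(A) <- 0
  dg <- pmax(rowSums(A), 1e-12)
  Lsym <- diag(C) - sweep(sweep(A, 1, sqrt(dg), "/"), 2, sqrt(dg), "/")
  ev <- eigen(Lsym, symmetric = TRUE)
  U <- ev$vectors[, C - seq_len(K) + 1, drop = FALSE]  # smallest K eigenvalues
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, 1e-12)
  stats::kmeans(U, centers = K, nstart = 5)$cluster
}

init_labels <- function(X, K, strategy) {
  C <- nrow(X)
  if (K > C) stop("more clusters than cells")
  set.seed(strategy$seed)
  labels <- switch(strategy$method,
    random = sample.int(K, C, replace = TRUE),
    kmeans = {
      Y <- transform_counts(X, strategy$transform)
      stats::kmeans(Y, centers = K, nstart = 5)$cluster
    },
    spectral = {
      Y <- transform_counts(X, strategy$transform)
      tryCatch(spectral_labels(Y, K, strategy$seed),
               error = function(e) {
                 warning("spectral clustering failed (", conditionMessage(e),
                         "); falling back to k-means")
                 stats::kmeans(Y, centers = K, nstart = 5)$cluster
               })
    })
  # guarantee every cluster is non-empty
  missing <- setdiff(seq_len(K), unique(labels))
  if (length(missing) > 0) {
    idx <- sample.int(C, length(missing))
    labels[idx] <- missing
  }
  labels
}

#' Moment-based starting parameters from clustering labels
#'
#' Cells are grouped by hard starting labels; within each group every gene
#' gets \eqn{\alpha} initialized at the group mean count, \eqn{\beta = 1},
#' and a dropout weight of 0.1 (the remaining 0.9 split over the NB
#' components).  Mixing weights start at the label proportions.
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param K,L model dimensions.
#' @param strategy an [init_strategy()].
#' @param scalers per-cell scalers (used only to de-scale group means).
#' @return a [zinb_params()] starting point.
#' @export
initialize_params <- function(counts, K, L = 2,
                              strategy = init_strategy("random"),
                              scalers = NULL) {
  counts <- as_count_matrix(counts)
  X <- counts$counts
  s <- expand_scalers(scalers, nrow(X))
  labels <- init_labels(X, K, strategy)
  params_from_labels(X, labels, K, L, s)
}

params_from_labels <- function(X, labels, K, L, s) {
  G <- ncol(X)
  dropout <- L >= 2
  n_nb <- L - as.integer(dropout)
  pi <- as.numeric(tabulate(labels, K)) / length(labels)
  q <- array(NA_real_, c(G, K, L))
  alpha <- array(NA_real_, c(G, K, n_nb))
  beta <- array(1, c(G, K, n_nb))
  q0 <- if (dropout) 0.1 else 0
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    mu <- if (length(idx) > 0) colMeans(X[idx, , drop = FALSE] / s[idx]) else colMeans(X / s)
    mu <- clip(mu, 0.05, .ALPHA_MAX)
    if (dropout) q[, k, 1] <- q0
    for (j in seq_len(n_nb)) {
      q[, k, as.integer(dropout) + j] <- (1 - q0) / n_nb
      # distinct starts per NB component so they can separate
      alpha[, k, j] <- mu / (2^(j - 1))
    }
  }
  sanitize_params(zinb_params(pi, q, alpha, beta, dropout = dropout))
}
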