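#' Specification of a simulated dataset
#'
#' Describes one draw from the generative model: cluster from \eqn{\pi} (or
#' fixed labels), mixture component from \eqn{q_{g,k,\cdot}}, then for NB
#' components a Gamma intensity and a Poisson count scaled by \eqn{s_c};
#' dropout components emit a hard zero.
#'
#' @param params generating [zinb_params()].
#' @param n_cells number of cells (ignored when `labels` is given).
#' @param scalers scalar or per-cell positive scalers (default 1).
#' @param labels optional fixed cluster labels (overrides draws from `pi`).
#' @param seed integer seed.
#' @return object of class `sim_spec`.
#' @export
simulation_spec <- function(params, n_cells = NULL, scalers = 1, labels = NULL,
                            seed = 1L) {
  validate_params(params)
  if (!is.null(labels)) n_cells <- length(labels)
  if (is.null(n_cells)) stop("give n_cells or labels")
  structure(list(params = params, n_cells = as.integer(n_cells),
                 scalers = scalers, labels = labels, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Draw counts from the generative model
#'
#' @param spec a [simulation_spec()].
#' @return object of class `zinb_sim`: `counts` (a [count_matrix()]),
#'   `labels` (true cluster per cell), `components` (C x G integer matrix,
#'   0 = dropout, j >= 1 = j-th NB component), `scalers`, `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  p <- spec$params
  C <- spec$n_cells; G <- p$G; K <- p$K
  set.seed(spec$seed)
  s <- expand_scalers(spec$scalers, C)
  labels <- spec$labels %||% sample.int(K, C, replace = TRUE, prob = p$pi)
  X <- matrix(0L, C, G)
  comp <- matrix(0L, C, G)
  l0 <- as.integer(p$dropout)
  for (g in seq_len(G)) {
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (length(idx) == 0) next
      l <- sample.int(p$L, length(idx), replace = TRUE, prob = p$q[g, k, ])
      comp[idx, g] <- l - l0            # dropout -> 0, NB comps -> 1..n_nb
      for (j in seq_len(p$n_nb)) {
        sel <- idx[l == l0 + j]
        if (length(sel) == 0) next
        lam <- stats::rgamma(length(sel), shape = p$alpha[g, k, j],
                             rate = p$beta[g, k, j])
        X[sel, g] <- stats::rpois(length(sel), s[sel] * lam)
      }
    }
  }
  structure(list(counts = count_matrix(X), labels = labels,
                 components = comp, scalers = s, spec = spec),
            class = "zinb_sim")
}

#' @export
print.zinb_sim <- function(x, ...) {
  cat(sprintf("zinb_sim: %d cells x %d genes, %d clusters, seed %d\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              x$spec$params$K, x$spec$seed))
  invisible(x)
}

#' The canonical two-gene, two-cluster benchmark
#'
#' Two genes, two cell types with mixing weights \eqn{\pi = (0.4, 0.6)},
#' dropout weight `q0` (default 0.2), NB weight `1 - q0`, all rates
#' \eqn{\beta = 1}, and shapes \eqn{\alpha}: cluster 1 `(10, 5)`, cluster 2
#' `(30, 20)` for genes 1 and 2.  Cell scalers are fixed at 1.
#'
#' @param n_cells number of cells to simulate.
#' @param q0 dropout weight in `[0, 1)`.
#' @param seed integer seed.
#' @return a [simulation_spec()].
#' @export
two_gene_benchmark_spec <- function(n_cells = 10000, q0 = 0.2, seed = 1L) {
  alpha <- array(c(10, 5, 30, 20), c(2, 2, 1))  # gene x cluster
  beta <- array(1, c(2, 2, 1))
  q <- array(c(rep(q0, 4), rep(1 - q0, 4)), c(2, 2, 2))
  params <- zinb_params(c(0.4, 0.6), q, alpha, beta)
  simulation_spec(params, n_cells, scalers = 1, seed = seed)
}

#' Standard EM starting values for the two-gene benchmark
#'
#' \eqn{\pi = (0.5, 0.5)}, dropout weight 0.1, NB weight 0.9, \eqn{\beta =
#' 1}, and \eqn{\alpha = (8, 8)} in cluster 1 and \eqn{(25, 25)} in cluster
#' 2.
#'
#' @return a [zinb_params()] starting point.
#' @export
two_gene_benchmark_init <- function() {
  alpha <- array(c(8, 8, 25, 25), c(2, 2, 1))
  beta <- array(1, c(2, 2, 1))
  q <- array(c(rep(0.1, 4), rep(0.9, 4)), c(2, 2, 2))
  zinb_params(c(0.5, 0.5), q, alpha, beta)
}

#' Spike differential expression into generating parameters
#'
#' Multiplies the NB mean (via \eqn{\alpha}) of the chosen genes by `fold`
#' in the target cluster, leaving all other parameters untouched, so the
#' spiked genes have a known mean ratio of exactly `fold` between the
#' target and the remaining clusters.
#'
#' @param params generating [zinb_params()].
#' @param genes integer indices of genes to spike (sampled without
#'   replacement by callers).
#' @param fold positive fold change (1.5 in the standard benchmark).
#' @param cluster target cluster index.
#' @return modified `zinb_params` with attribute `spiked_genes`.
#' @export
spike_deg <- function(params, genes, fold, cluster) {
  validate_params(params)
  if (length(genes) > params$G) stop("more spiked genes than genes")
  if (any(genes < 1 | genes > params$G)) stop("gene index out of range")
  stopifnot(fold > 0, cluster >= 1, cluster <= params$K)
  params$alpha[genes, cluster, ] <- params$alpha[genes, cluster, ] * fold
  attr(params, "spiked_genes") <- genes
  params
}

#' Inject dropout into an existing count matrix
#'
#' Independently zeroes each entry with its cell's cluster-specific dropout
#' probability; complements building the dropout weight into the generative
#' parameters.
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param q0 scalar dropout probability, or one value per cluster.
#' @param labels cluster labels (required when `q0` is per-cluster).
#' @param seed integer seed.
#' @return a new `count_matrix`.
#' @export
apply_dropout <- function(counts, q0, labels = NULL, seed = 1L) {
  counts <- as_count_matrix(counts)
  X <- counts$counts
  if (any(q0 < 0 | q0 > 1)) stop("dropout probabilities must lie in [0, 1]")
  if (length(q0) > 1) {
    if (is.null(labels)) stop("labels required for per-cluster dropout")
    if (length(labels) != nrow(X)) stop("labels length mismatch")
    pc <- q0[labels]
  } else {
    pc <- rep(q0, nrow(X))
  }
  set.seed(seed)
  drop <- matrix(stats::runif(length(X)) < pc, nrow(X), ncol(X))
  X[drop] <- 0
  count_matrix(X, counts$cell_ids, counts$gene_ids)
}

#' Three-cluster benchmark with spiked DEG and per-cluster dropout
#'
#' A packaged stand-in for the benchmark built from real cortex fits: gene
#' level NB parameters are drawn once (per seed) from log-normal ranges
#' matching typical scRNA-seq per-gene fits (\eqn{\alpha} centered near 2,
#' \eqn{\beta} near 1), `n_deg` genes are spiked `fold`-times higher in
#' cluster 1, and each cluster receives its own dropout weight (default
#' mean 0.1, stepped by 0.05 per cluster).
#'
#' @param n_genes number of genes.
#' @param cells_per_cluster cells in each of the three clusters.
#' @param n_deg number of spiked genes.
#' @param fold spiked fold change.
#' @param q0 length-3 per-cluster dropout weights (or a scalar).
#' @param seed integer seed.
#' @return list: `sim` (a `zinb_sim`), `deg_genes` (spiked gene ids),
#'   `params` (generating parameters after spiking).
#' @export
three_cluster_benchmark <- function(n_genes = 1000, cells_per_cluster = 400,
                                    n_deg = 150, fold = 1.5,
                                    q0 = c(0.05, 0.10, 0.15), seed = 1L) {
  stopifnot(n_deg <= n_genes)
  K <- 3L
  q0 <- rep_len(q0, K)
  set.seed(child_seed(seed, 77L))
  alpha_g <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 0.8)
  beta_g <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
  alpha <- array(rep(alpha_g, K), c(n_genes, K, 1))
  beta <- array(rep(beta_g, K), c(n_genes, K, 1))
  q <- array(NA_real_, c(n_genes, K, 2))
  for (k in seq_len(K)) {
    q[, k, 1] <- q0[k]
    q[, k, 2] <- 1 - q0[k]
  }
  params <- zinb_params(rep(1 / K, K), q, alpha, beta)
  deg_idx <- sample.int(n_genes, n_deg)
  params <- spike_deg(params, deg_idx, fold, cluster = 1L)
  labels <- rep(seq_len(K), each = cells_per_cluster)
  spec <- simulation_spec(params, labels = labels, scalers = 1,
                          seed = child_seed(seed, 78L))
  sim <- simulate_counts(spec)
  list(sim = sim, deg_genes = sim$counts$gene_ids[deg_idx], params = params)
}
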