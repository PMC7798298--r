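# shared fixtures built in code

# small random but valid parameter set
random_params <- function(G = 2, K = 2, L = 2, seed = 1) {
  set.seed(seed)
  dropout <- L >= 2
  n_nb <- L - as.integer(dropout)
  pi <- as.numeric(stats::rgamma(K, 2)); pi <- pi / sum(pi)
  q <- array(stats::rgamma(G * K * L, 2), c(G, K, L))
  qs <- apply(q, c(1, 2), sum)
  q <- q / array(rep(qs, L), dim(q))
  alpha <- array(stats::runif(G * K * n_nb, 0.5, 20), c(G, K, n_nb))
  beta <- array(stats::runif(G * K * n_nb, 0.3, 3), c(G, K, n_nb))
  zinb_params(pi, q, alpha, beta, dropout = dropout)
}

# tiny deterministic count matrix
toy_counts <- function(C = 3, G = 2, seed = 4) {
  set.seed(seed)
  count_matrix(matrix(rpois(C * G, 4), C, G))
}

# brute-force log pmf of one gene/cluster mixture term via direct summation
brute_gene_log_prob <- function(x, g, k, params, s = 1) {
  total <- 0
  if (params$dropout && x == 0) total <- total + params$q[g, k, 1]
  l0 <- as.integer(params$dropout)
  for (j in seq_len(params$n_nb)) {
    a <- params$alpha[g, k, j]; b <- params$beta[g, k, j]
    total <- total + params$q[g, k, l0 + j] *
      exp(lgamma(x + a) - lgamma(a) - lgamma(x + 1) +
            a * log(b / (b + s)) + x * log(s / (b + s)))
  }
  log(total)
}

# brute-force per-cell totals, summing over clusters in the linear domain
brute_cell_totals <- function(X, params, s) {
  C <- nrow(X)
  out <- numeric(C)
  joint <- matrix(0, C, params$K)
  for (c in seq_len(C)) {
    for (k in seq_len(params$K)) {
      lp <- log(params$pi[k])
      for (g in seq_len(ncol(X))) {
        lp <- lp + brute_gene_log_prob(X[c, g], g, k, params, s[c])
      }
      joint[c, k] <- lp
    }
    m <- max(joint[c, ])
    out[c] <- m + log(sum(exp(joint[c, ] - m)))
  }
  list(joint = joint, total = out)
}
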