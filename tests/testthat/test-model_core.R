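test_that("cell scalers follow library size / target", {
  cm <- count_matrix(rbind(c(6000, 4000), c(2500, 2500)))
  s <- compute_cell_scalers(cm)
  expect_equal(s, c(1, 0.5), ignore_attr = TRUE)
  cm0 <- count_matrix(rbind(c(1, 1), c(0, 0)))
  expect_error(compute_cell_scalers(cm0), "zero library size")
})

test_that("nb_log_pmf matches its closed form and normalizes", {
  expect_equal(nb_log_pmf(0, 1, 1, 1), log(0.5))
  expect_equal(sum(exp(nb_log_pmf(0:2000, 2.5, 1.3, 2))), 1, tolerance = 1e-8)
  expect_error(nb_log_pmf(2.5, 1, 1), "integer")
  expect_error(nb_log_pmf(-1, 1, 1), "integer")
})

test_that("nb_log_pmf agrees with quadrature of the Gamma-Poisson integral", {
  # independent oracle: numerically integrate the printed integral
  quad <- function(x, a, b, s) {
    f <- function(lam) dgamma(lam, shape = a, rate = b) * dpois(x, s * lam)
    stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value
  }
  cases <- list(c(3, 2, 1, 1), c(0, 1, 1, 1), c(7, 2.5, 1.3, 2),
                c(12, 0.7, 0.4, 0.5), c(1, 30, 1, 1))
  for (cs in cases) {
    expect_equal(exp(nb_log_pmf(cs[1], cs[2], cs[3], cs[4])),
                 quad(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-8)
  }
})

test_that("NB mean identity holds", {
  x <- 0:5000
  for (ab in list(c(2, 1), c(0.8, 0.5), c(5, 2))) {
    mu <- sum(x * exp(nb_log_pmf(x, ab[1], ab[2], 1.5)))
    expect_equal(mu, 1.5 * ab[1] / ab[2], tolerance = 1e-6)
  }
})

test_that("gene_cluster_log_prob has indicator semantics and matches brute force", {
  p <- random_params(G = 2, K = 2, L = 3, seed = 7)
  # dropout term vanishes for positive counts
  expect_equal(gene_cluster_log_prob(5, 1, 1, p),
               brute_gene_log_prob(5, 1, 1, p), tolerance = 1e-10)
  # pure dropout gives probability one at zero
  q <- array(c(1, 1e-12), c(1, 1, 2)); q <- q / sum(q)
  pd <- zinb_params(1, q, 2, 1)
  expect_equal(gene_cluster_log_prob(0, 1, 1, pd), 0, tolerance = 1e-10)
  # random params, counts up to 50: brute-force summation oracle
  for (seed in 1:3) {
    pp <- random_params(G = 2, K = 2, L = sample(2:3, 1), seed = seed)
    for (x in c(0L, 1L, 3L, 17L, 50L)) {
      expect_equal(gene_cluster_log_prob(x, 2, 1, pp, s = 1.3),
                   brute_gene_log_prob(x, 2, 1, pp, s = 1.3), tolerance = 1e-10)
    }
  }
})

test_that("cell_log_likelihoods matches brute force and is invariant", {
  p <- random_params(G = 2, K = 2, L = 2, seed = 2)
  cm <- toy_counts(C = 3, G = 2)
  res <- cell_log_likelihoods(cm, p, scalers = c(1, 0.7, 2))
  ref <- brute_cell_totals(cm$counts, p, c(1, 0.7, 2))
  expect_equal(res$total, ref$total, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$log_joint, ref$joint, tolerance = 1e-10, ignore_attr = TRUE)

  # K = 1 degenerate mixture
  p1 <- random_params(G = 2, K = 1, L = 2, seed = 3)
  r1 <- cell_log_likelihoods(cm, p1)
  expect_equal(r1$total, r1$log_joint[, 1], ignore_attr = TRUE)

  # scaling pi then renormalizing leaves totals unchanged (already normalized)
  # and relabeling clusters with their parameters leaves totals unchanged
  pperm <- zinbmix:::permute_clusters(p, c(2, 1))
  expect_equal(cell_log_likelihoods(cm, pperm)$total,
               cell_log_likelihoods(cm, p)$total, tolerance = 1e-10)
})

test_that("dataset_log_likelihood sums per-cell totals, exchangeably", {
  p <- random_params(seed = 5)
  cm <- toy_counts(C = 5, G = 2, seed = 9)
  ll <- dataset_log_likelihood(cm, p)
  expect_equal(ll, sum(cell_log_likelihoods(cm, p)$total))
  perm <- c(3, 1, 5, 2, 4)
  cmp <- count_matrix(cm$counts[perm, ])
  expect_equal(dataset_log_likelihood(cmp, p), ll, tolerance = 1e-12)
  one <- count_matrix(cm$counts[2, , drop = FALSE])
  expect_equal(dataset_log_likelihood(one, p),
               cell_log_likelihoods(cm, p)$total[2], tolerance = 1e-12)
})

test_that("zero_probability matches closed form, general evaluation, and simulation", {
  # direct arithmetic from the printed formula
  pd <- zinb_params(1, c(0.2, 0.8), 1, 1)
  expect_equal(zero_probability(1, 1, pd, s = 1), 0.2 + 0.8 * 0.5)
  # pure dropout
  qd <- array(c(1 - 1e-12, 1e-12), c(1, 1, 2))
  expect_equal(zero_probability(1, 1, zinb_params(1, qd, 1, 1)), 1, tolerance = 1e-10)
  # closed form == exp(gene_cluster_log_prob(0, .)) for random parameter sets
  for (seed in 1:5) {
    p <- random_params(G = 2, K = 2, L = sample(2:3, 1), seed = seed)
    for (s in c(0.5, 1, 2)) {
      expect_equal(zero_probability(1, 2, p, s),
                   exp(gene_cluster_log_prob(0, 1, 2, p, s)), tolerance = 1e-12)
    }
  }
  # simulation oracle: empirical zero fraction of 1e6 draws
  p <- random_params(G = 1, K = 1, L = 2, seed = 11)
  set.seed(42)
  n <- 1e6
  l <- sample(1:2, n, replace = TRUE, prob = p$q[1, 1, ])
  x <- integer(n)
  nb <- l == 2
  x[nb] <- rpois(sum(nb), rgamma(sum(nb), p$alpha[1, 1, 1], rate = p$beta[1, 1, 1]))
  p0 <- zero_probability(1, 1, p, 1)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(x == 0) - p0), 3 * se)
})
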