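test_that("e_step posteriors obey symmetry, indicator rule and Bayes rule", {
  cm <- toy_counts(C = 3, G = 2)
  # identical per-cluster parameters with pi = (.5, .5) -> gamma = .5
  p1 <- random_params(G = 2, K = 1, L = 2, seed = 1)
  # symmetric parameters: both clusters share cluster 1 of p1
  q <- array(NA_real_, c(2, 2, 2))
  q[, 1, ] <- p1$q[, 1, ]; q[, 2, ] <- p1$q[, 1, ]
  psym <- zinb_params(c(0.5, 0.5), q,
                      array(rep(p1$alpha[, 1, 1], 2), c(2, 2, 1)),
                      array(rep(p1$beta[, 1, 1], 2), c(2, 2, 1)))
  es <- e_step(cm, psym)
  expect_equal(as.vector(es$gamma), rep(0.5, 6), tolerance = 1e-12)

  # dropout posterior is exactly zero for positive counts
  p <- random_params(G = 2, K = 2, L = 2, seed = 2)
  es2 <- e_step(cm, p)
  pos <- cm$counts > 0
  for (k in 1:2) expect_true(all(es2$comp_post[, , k, 1][pos] == 0))
  # rows of gamma and comp_post sum to one
  expect_equal(rowSums(es2$gamma), rep(1, 3), tolerance = 1e-8)
  expect_equal(as.vector(apply(es2$comp_post, c(1, 2, 3), sum)),
               rep(1, 3 * 2 * 2), tolerance = 1e-8)

  # gamma matches direct Bayes-rule arithmetic
  ref <- brute_cell_totals(cm$counts, p, rep(1, 3))
  gamma_ref <- exp(ref$joint - ref$total)
  expect_equal(es2$gamma, gamma_ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("m_step reproduces counting updates for hard responsibilities", {
  set.seed(3)
  cm <- toy_counts(C = 40, G = 2, seed = 3)
  p <- random_params(G = 2, K = 2, L = 2, seed = 3)
  labels <- rep(1:2, each = 20)
  gamma <- cbind(labels == 1, labels == 2) * 1
  es <- e_step(cm, p)
  es$gamma <- gamma
  newp <- m_step(cm, es, p)
  expect_equal(newp$pi, c(0.5, 0.5), tolerance = 1e-9)

  # all component mass on the NB component -> q_nb = 1 (up to floors)
  es2 <- es
  es2$comp_post[, , , 1] <- 0
  es2$comp_post[, , , 2] <- 1
  newp2 <- m_step(cm, es2, p)
  expect_equal(as.vector(newp2$q[, , 2]), rep(1, 4), tolerance = 1e-8)
})

test_that("K=1, L=1 m_step equals an independent direct NB MLE", {
  set.seed(4)
  x <- rnbinom(500, size = 3, mu = 6)
  cm <- count_matrix(matrix(x, ncol = 1))
  p0 <- zinb_params(1, 1, 2, 1, dropout = FALSE)
  es <- e_step(cm, p0)
  fitp <- m_step(cm, es, p0)
  # oracle: generic optimizer on the same unweighted objective, different
  # parameterization and starting point
  nll <- function(par) -sum(nb_log_pmf(x, exp(par[1]), exp(par[2]), 1))
  ora <- optim(c(0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  expect_equal(fitp$alpha[1, 1, 1], exp(ora$par[1]), tolerance = 1e-3)
  expect_equal(fitp$beta[1, 1, 1], exp(ora$par[2]), tolerance = 1e-3)
})

test_that("fit_em respects max_iter and produces monotone traces", {
  sim <- simulate_counts(two_gene_benchmark_spec(300, 0.2, seed = 5))
  f1 <- fit_em(sim$counts, 2, 2, init = two_gene_benchmark_init(), max_iter = 1)
  expect_equal(f1$n_iter, 1)
  expect_false(f1$converged)

  # EM monotonicity on several random inputs and initializations
  for (seed in 1:3) {
    sm <- simulate_counts(two_gene_benchmark_spec(200, 0.3, seed = seed))
    ft <- fit_em(sm$counts, 2, 2, init = init_strategy("random", seed = seed),
                 max_iter = 25)
    expect_true(all(diff(ft$loglik_trace) >= -1e-6 * abs(ft$loglik_trace[-1])))
  }
})

test_that("label switching leaves the final log likelihood unchanged", {
  sim <- simulate_counts(two_gene_benchmark_spec(400, 0.2, seed = 6))
  init <- two_gene_benchmark_init()
  f_a <- fit_em(sim$counts, 2, 2, init = init, max_iter = 60)
  f_b <- fit_em(sim$counts, 2, 2, init = zinbmix:::permute_clusters(init, c(2, 1)),
                max_iter = 60)
  expect_equal(f_a$loglik, f_b$loglik, tolerance = 1e-6)
  perm <- match_clusters(f_b$params, f_a$params)
  expect_equal(f_b$params$pi[perm], f_a$params$pi, tolerance = 1e-4)
})

test_that("L=1 without dropout reproduces independent per-gene NB fits", {
  set.seed(7)
  X <- cbind(rnbinom(400, size = 2, mu = 4), rnbinom(400, size = 5, mu = 10))
  cm <- count_matrix(X)
  fit <- fit_em(cm, K = 1, L = 1,
                init = zinb_params(1, array(1, c(2, 1, 1)),
                                   array(c(1, 1), c(2, 1, 1)),
                                   array(1, c(2, 1, 1)), dropout = FALSE),
                max_iter = 50)
  for (g in 1:2) {
    nll <- function(par) {
      ab <- pmin(pmax(exp(par), 1e-8), 1e8)
      -sum(nb_log_pmf(X[, g], ab[1], ab[2], 1))
    }
    ora <- optim(c(0, 0), nll, method = "BFGS", control = list(maxit = 500))
    expect_equal(fit$params$alpha[g, 1, 1], exp(ora$par[1]), tolerance = 1e-3)
    expect_equal(fit$params$beta[g, 1, 1], exp(ora$par[2]), tolerance = 1e-3)
  }
})

test_that("multi_restart_fit picks the best candidate and is reproducible", {
  sim <- simulate_counts(two_gene_benchmark_spec(300, 0.2, seed = 8))
  one <- multi_restart_fit(sim$counts, 2, 2, n_random_restarts = 1, seed = 9,
                           max_iter = 40)
  same <- multi_restart_fit(sim$counts, 2, 2, n_random_restarts = 1, seed = 9,
                            max_iter = 40)
  expect_equal(one$loglik, same$loglik)
  multi <- multi_restart_fit(sim$counts, 2, 2, n_random_restarts = 4, seed = 9,
                             max_iter = 40)
  expect_true(all(multi$loglik >= multi$candidate_logliks - 1e-9))
})

test_that("initialization is deterministic and recovers separable structure", {
  s1 <- initialize_params(toy_counts(30, 2, 1), 2, 2, init_strategy("random", seed = 3))
  s2 <- initialize_params(toy_counts(30, 2, 1), 2, 2, init_strategy("random", seed = 3))
  expect_identical(s1, s2)
  expect_silent(zinbmix:::validate_params(s1))

  # perfectly separated clusters: kmeans initialization finds the proportions
  set.seed(10)
  X <- rbind(matrix(rpois(60 * 2, 2), 60, 2), matrix(rpois(40 * 2, 60), 40, 2))
  p <- initialize_params(count_matrix(X), 2, 2, init_strategy("kmeans", "log1p", 1))
  expect_equal(sort(p$pi), c(0.4, 0.6), tolerance = 1e-9)

  expect_error(initialize_params(toy_counts(3, 2), 5, 2), "more clusters than cells")
  # the eight standard conditions
  strat <- default_init_strategies(1)
  expect_length(strat, 8)
  expect_setequal(vapply(strat, function(s) paste(s$method, s$transform), ""),
                  as.vector(outer(c("kmeans", "spectral"),
                                  c("log1p", "pca2", "pca_25pct", "pca_40pct"),
                                  paste)))
})
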