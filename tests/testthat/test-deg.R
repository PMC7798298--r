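# direct reimplementation of the weighted moments for the oracle route
direct_moments <- function(x, w, v) {
  pos <- x > 0
  denom <- sum(w[pos]) + sum((w * v)[!pos])
  m <- sum((w * x)[pos]) / denom
  e2 <- sum((w * x^2)[pos]) / denom
  list(m = m, var = e2 - m^2, n_eff = denom)
}

test_that("expression_moments reduces correctly under hard labels", {
  # cluster with counts {0, 2, 4}, w = 1, v = 1: m = 2, E(x^2) = 20/3
  X <- matrix(c(0, 2, 4), ncol = 1)
  cm <- count_matrix(X)
  gamma <- matrix(1, 3, 1)
  comp_post <- array(0, c(3, 1, 1, 2))
  comp_post[, , 1, 2] <- 1  # v = 1 - p(dropout) = 1 everywhere
  mom <- expression_moments(cm, gamma, comp_post, 1)
  expect_equal(mom$m, 2)
  expect_equal(mom$second_moment, 20 / 3)
  expect_equal(mom$var, 20 / 3 - 4)
  expect_equal(mom$n_eff, 3)

  # all positive counts with w = 1 -> plain sample mean
  Xp <- matrix(c(1, 2, 6), ncol = 1)
  cmp2 <- count_matrix(Xp)
  momp <- expression_moments(cmp2, gamma, comp_post, 1)
  expect_equal(momp$m, 3)

  # v = 0 at zero counts -> zeros vanish from the denominator
  comp_post0 <- comp_post
  comp_post0[X == 0, 1, 1, 1] <- 1
  comp_post0[X == 0, 1, 1, 2] <- 0
  mom0 <- expression_moments(cm, gamma, comp_post0, 1)
  expect_equal(mom0$m, 3)  # mean over positive counts only
  expect_equal(mom0$n_eff, 2)
})

test_that("soft-weighted moments match a direct implementation", {
  set.seed(1)
  C <- 50
  X <- matrix(rpois(C * 3, 3), C, 3)
  cm <- count_matrix(X)
  gamma <- matrix(runif(C * 2), C, 2)
  gamma <- gamma / rowSums(gamma)
  comp_post <- array(0, c(C, 3, 2, 2))
  v <- matrix(runif(C * 3), C, 3)
  v[X > 0] <- 1
  for (k in 1:2) {
    comp_post[, , k, 1] <- 1 - v
    comp_post[, , k, 2] <- v
  }
  for (k in 1:2) {
    mom <- expression_moments(cm, gamma, comp_post, k)
    for (g in 1:3) {
      ref <- direct_moments(X[, g], gamma[, k], v[, g])
      expect_equal(mom$m[g], ref$m, tolerance = 1e-12)
      expect_equal(mom$var[g], ref$var, tolerance = 1e-12)
      expect_equal(mom$n_eff[g], ref$n_eff, tolerance = 1e-12)
    }
  }
})

test_that("wald test symmetry and degenerate cases", {
  mA <- data.frame(gene_id = "g1", m = 2, var = 1, n_eff = 10)
  mB <- data.frame(gene_id = "g1", m = 3, var = 2, n_eff = 20)
  ab <- wald_deg_test(mA, mB)
  ba <- wald_deg_test(mB, mA)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  same <- wald_deg_test(mA, mA)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  zeroA <- data.frame(gene_id = "g1", m = 2, var = 0, n_eff = 10)
  expect_equal(wald_deg_test(zeroA, zeroA)$p, 1)
  zeroB <- data.frame(gene_id = "g1", m = 3, var = 0, n_eff = 10)
  expect_warning(res <- wald_deg_test(zeroA, zeroB), "zero pooled variance")
  expect_equal(res$p, 0)
})

test_that("wald type-I error is near nominal for hard labels at large n", {
  set.seed(2)
  n <- 120
  n_genes <- 2000
  rej <- logical(n_genes)
  gamma <- matrix(1, n, 1)
  comp_post <- array(0, c(n, 1, 1, 2)); comp_post[, , 1, 2] <- 1
  for (g in seq_len(n_genes)) {
    xa <- rpois(n, 20); xb <- rpois(n, 20)  # same law in both groups
    ma <- expression_moments(count_matrix(matrix(xa, ncol = 1)), gamma, comp_post, 1)
    mb <- expression_moments(count_matrix(matrix(xb, ncol = 1)), gamma, comp_post, 1)
    rej[g] <- wald_deg_test(ma, mb)$p < 0.05
  }
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("Benjamini-Hochberg equals the hand-executed step-up and p.adjust", {
  expect_equal(benjamini_hochberg(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  p <- c(0.01, 0.04, 0.03, 0.005)
  # hand-executed: sorted (0.005,0.01,0.03,0.04) * 4/(1..4) -> (.02,.02,.04,.04)
  expect_equal(benjamini_hochberg(p), c(0.02, 0.04, 0.04, 0.02))
  set.seed(3)
  pr <- runif(200)
  expect_equal(benjamini_hochberg(pr), p.adjust(pr, "BH"))
  # invariance to input order
  perm <- sample(200)
  expect_equal(benjamini_hochberg(pr[perm]), benjamini_hochberg(pr)[perm])
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("deg_between_clusters validates inputs and ranks spiked genes first", {
  bench <- three_cluster_benchmark(n_genes = 120, cells_per_cluster = 150,
                                   n_deg = 30, fold = 1.5,
                                   q0 = c(0.05, 0.1, 0.15), seed = 4)
  sim <- bench$sim
  # fit with hard labels known: start EM from the true-label moment seed
  init <- zinbmix:::params_from_labels(sim$counts$counts, sim$labels, 3, 2,
                                       rep(1, nrow(sim$counts$counts)))
  fit <- fit_em(sim$counts, 3, 2, init = init, max_iter = 12, scalers = 1)
  expect_error(deg_between_clusters(sim$counts, fit, 2, 2), "distinct")
  tab <- deg_between_clusters(sim$counts, fit, 1, 3)
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
  expect_true(!is.unsorted(tab$p_adjusted))
  auc <- deg_auc(tab, bench$deg_genes)
  expect_gt(auc, 0.9)
})
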