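# zinbmix

Joint soft clustering, differential expression and zero imputation for
single-cell RNA-seq counts under a generalized zero-inflated negative
binomial (ZINB) mixture model, fitted by expectation-maximization on the
raw counts — no prior imputation, no log transformation.

## Who this is for

Analysts of scRNA-seq UMI/read count matrices who want cell-type discovery
and differential expression that *model* dropout (detection failures
producing spurious zeros) instead of imputing around it, and methodologists
benchmarking dropout-aware mixture models on simulated data with known
ground truth.

## The model

The count of gene *g* in a cell of type *k* follows a mixture over *L*
components:

```
f_k(x_g) = q_{g,k,0} 1{x_g = 0} + sum_{l>=1} q_{g,k,l} NB(x_g; alpha_{g,k,l}, beta_{g,k,l}, s_c)
```

Component 0 is a point mass at zero (dropout); each NB component is a
Gamma–Poisson mixture — a Poisson intensity `lambda ~ Gamma(alpha, beta)`
scaled by the cell scaler `s_c` (library size / 10,000 for real data) —
with closed-form log PMF

```
log NB(x) = lgamma(x+alpha) - lgamma(alpha) - lgamma(x+1)
          + alpha*log(beta/(beta+s)) + x*log(s/(beta+s)).
```

A cell's likelihood is `sum_k pi_k prod_g f_k(x_g)`. EM alternates:

* **E-step** — cluster posteriors `gamma_{c,k} = p(k|x_c)` (soft clusters)
  and per-entry component posteriors `p(l|k, x_{c,g})`;
* **M-step** — closed-form updates for `pi` and `q`, and a warm-started
  quasi-Newton maximization of the responsibility-weighted NB likelihood
  for each `(alpha, beta)`.

The number of cell types is chosen by AIC/BIC over a range of K.
Differential expression between two clusters uses soft-weighted conditional
moments (weights `w = p(k|x_c)`, and for zeros `v = 1 - p(dropout|k,x)`),
a Wald z statistic, and Benjamini–Hochberg adjustment. Observed zeros can
be imputed by their posterior mean for visualization only.

## Worked example

```r
library(zinbmix)

# two genes, two cell types, 20% dropout -- the canonical benchmark
spec <- two_gene_benchmark_spec(n_cells = 5000, q0 = 0.2, seed = 1)
sim  <- simulate_counts(spec)

# automatic cluster-number selection
sel <- select_num_clusters(sim$counts, K_range = 1:5, restarts_per_K = 10,
                           seed = 1, max_iter = 60)
sel$K_best
#> [1] 2
sel$table[, c("K", "loglik", "AIC", "BIC")]
#>   K    loglik      AIC      BIC
#> 1 1 -34712.47 69436.94 69476.04
#> 2 2 -32483.99 64993.98 65078.70
#> 3 3 -32482.17 65004.34 65134.69
#> 4 4 -32480.71 65015.42 65191.39
#> 5 5 -32479.19 65026.39 65247.97

# the likelihood stops improving past K = 2; AIC and BIC both pick 2.

fit <- fit_em(sim$counts, K = 2, L = 2, init = two_gene_benchmark_init())
fit$params$pi            # generating proportions were (0.4, 0.6)
#> [1] 0.3906433 0.6093567
labels <- hard_assign(fit)
adjusted_rand_index(labels, sim$labels)
#> [1] 0.8217012

deg <- deg_between_clusters(sim$counts, fit, 1, 2)
head(deg[, c("gene_id", "m_k1", "m_k2", "wald_z", "p_adjusted")], 2)
#>   gene_id      m_k1     m_k2    wald_z p_adjusted
#> 1   gene1 10.096637 29.97104 -102.5579          0
#> 2   gene2  5.033657 20.14508 -102.6653          0

imp <- impute_zeros(sim$counts, fit)      # zeros -> posterior means
```

The conditional means recover the generating NB means (10, 30) and (5, 20)
with overwhelming Wald evidence for the difference; the ARI of 0.82 against
the true labels reflects the residual overlap the 20% dropout induces.

## Command line

`inst/cli/zinbmix` exposes `simulate`, `fit`, `select-k`, `cluster`, `deg`,
`impute` and `validate` subcommands over CSV/TSV/MatrixMarket matrices; see
`?zinbmix_cli`.
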