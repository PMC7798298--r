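#' Soft-weighted conditional expression moments for one cluster
#'
#' For cluster `k`, each cell contributes with weight \eqn{w_{c,k} = p(k \mid
#' x_c)}; observed zeros additionally carry \eqn{v_{c,g,k} = 1 - p(l =
#' \mathrm{dropout} \mid k, x_{c,g})}, the probability that the zero is a
#' true (expressed) zero rather than dropout.  The conditional mean is
#' \deqn{m_{g,k} = \frac{\sum_{x>0} w\,x}{\sum_{x>0} w + \sum_{x=0} w\,v},}
#' and the second moment uses the same weights and denominator; the variance
#' is \eqn{E(x^2) - E(x)^2}.
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param gamma C x K cluster posterior matrix.
#' @param comp_post C x G x K x L component posterior array (from
#'   [e_step()]).
#' @param k cluster index.
#' @return data.frame with one row per gene: `gene_id`, `m`,
#'   `second_moment`, `var`, `n_eff`, `defined`.
#' @export
expression_moments <- function(counts, gamma, comp_post, k) {
  counts <- as_count_matrix(counts)
  X <- counts$counts
  C <- nrow(X); G <- ncol(X)
  w <- gamma[, k]
  L <- dim(comp_post)[4]
  dropout <- L >= 2
  # v = 1 - p(dropout | k, x); equals 1 automatically where x > 0
  v <- if (dropout) 1 - comp_post[, , k, 1] else matrix(1, C, G)
  pos <- X > 0
  W <- matrix(w, C, G)
  num <- colSums(W * X * pos)
  denom <- colSums(W * pos) + colSums(W * v * (!pos))
  m <- num / denom
  e2 <- colSums(W * X^2 * pos) / denom
  vr <- e2 - m^2
  vr[vr > -1e-8 & vr < 0] <- 0
  defined <- denom > 1e-10 & is.finite(m)
  data.frame(gene_id = counts$gene_ids, m = m, second_moment = e2, var = vr,
             n_eff = denom, defined = defined, row.names = NULL)
}

#' Wald test between two sets of cluster moments
#'
#' \eqn{z = (m_A - m_B)/\sqrt{\sigma^2_A/n_A + \sigma^2_B/n_B}} with the
#' effective sample sizes from the moment denominators; two-sided normal
#' p-value.  Zero pooled variance gives `z = 0, p = 1` when means agree and
#' `p = 0` (with a warning) when they differ.
#'
#' @param mA,mB data.frames from [expression_moments()] (same gene order).
#' @return data.frame with `gene_id`, `z`, `p`.
#' @export
wald_deg_test <- function(mA, mB) {
  stopifnot(nrow(mA) == nrow(mB))
  se2 <- mA$var / mA$n_eff + mB$var / mB$n_eff
  diff <- mA$m - mB$m
  z <- numeric(nrow(mA))
  p <- numeric(nrow(mA))
  zero_se <- se2 <= 0
  if (any(zero_se & diff != 0, na.rm = TRUE)) {
    warning("zero pooled variance with unequal means; p set to 0")
  }
  z[!zero_se] <- diff[!zero_se] / sqrt(se2[!zero_se])
  z[zero_se & diff != 0] <- Inf * sign(diff[zero_se & diff != 0])
  p <- 2 * stats::pnorm(-abs(z))
  p[zero_se & diff == 0] <- 1
  data.frame(gene_id = mA$gene_id, z = z, p = p, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up procedure: sort p-values increasingly, multiply by
#' `m/rank`, enforce monotonicity from the largest down, clip at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Differential expression between two clusters
#'
#' Composes [e_step()] responsibilities from a fitted model with
#' [expression_moments()], [wald_deg_test()] and [benjamini_hochberg()].
#' Genes with undefined moments in either cluster are dropped (count
#' reported via a message).
#'
#' @param counts `count_matrix` or coercible matrix (the matrix the model
#'   was fitted to).
#' @param fit a `zinb_fit` (or a `zinb_params` for externally supplied
#'   responsibilities via `gamma`).
#' @param k1,k2 distinct cluster indices.
#' @param scalers per-cell scalers (defaults to those stored in the fit).
#' @return data.frame sorted by adjusted p-value with columns `gene_id`,
#'   `m_k1`, `m_k2`, `var_k1`, `var_k2`, `n_eff_k1`, `n_eff_k2`, `wald_z`,
#'   `p_value`, `p_adjusted`.
#' @export
deg_between_clusters <- function(counts, fit, k1, k2, scalers = NULL) {
  if (k1 == k2) stop("k1 and k2 must be distinct clusters")
  counts <- as_count_matrix(counts)
  params <- if (inherits(fit, "zinb_fit")) fit$params else fit
  if (is.null(scalers) && inherits(fit, "zinb_fit")) scalers <- fit$scalers
  if (k1 < 1 || k1 > params$K || k2 < 1 || k2 > params$K) stop("cluster index out of range")
  es <- e_step(counts, params, scalers)
  mA <- expression_moments(counts, es$gamma, es$comp_post, k1)
  mB <- expression_moments(counts, es$gamma, es$comp_post, k2)
  keep <- mA$defined & mB$defined
  if (any(!keep)) message(sum(!keep), " gene(s) with undefined moments dropped")
  mA <- mA[keep, ]; mB <- mB[keep, ]
  wt <- wald_deg_test(mA, mB)
  out <- data.frame(gene_id = mA$gene_id,
                    m_k1 = mA$m, m_k2 = mB$m,
                    var_k1 = mA$var, var_k2 = mB$var,
                    n_eff_k1 = mA$n_eff, n_eff_k2 = mB$n_eff,
                    wald_z = wt$z, p_value = wt$p,
                    p_adjusted = benjamini_hochberg(wt$p),
                    row.names = NULL)
  out[order(out$p_adjusted, out$p_value, out$gene_id), ]
}

#' Rank-based AUC of a DEG ranking against a known truth set
#'
#' Standard Wilcoxon/Mann-Whitney estimator of the area under the ROC curve
#' when genes are ranked by increasing p-value.
#'
#' @param deg_table data.frame from [deg_between_clusters()].
#' @param true_deg character vector of truly differential gene ids.
#' @return AUC in `[0, 1]`.
#' @export
deg_auc <- function(deg_table, true_deg) {
  is_pos <- deg_table$gene_id %in% true_deg
  if (!any(is_pos) || all(is_pos)) stop("truth set must be a proper subset of tested genes")
  score <- -rank(deg_table$p_value, ties.method = "average")  # higher = more DE
  r <- rank(score, ties.method = "average")
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
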