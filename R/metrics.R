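#' Hard cluster assignment from soft posteriors
#'
#' Assigns each cell to the cluster with the highest posterior probability;
#' ties break toward the smallest cluster index.
#'
#' @param gamma C x K matrix of cluster posteriors (rows sum to 1), or a
#'   `zinb_fit` whose `gamma` is used.
#' @return integer vector of cluster labels in `1..K`.
#' @export
hard_assign <- function(gamma) {
  if (inherits(gamma, "zinb_fit")) gamma <- gamma$gamma
  gamma <- as.matrix(gamma)
  if (nrow(gamma) == 0 || ncol(gamma) == 0) stop("empty posterior matrix")
  max.col(gamma, ties.method = "first")
}

#' Adjusted Rand index
#'
#' Permutation-model chance-corrected agreement between two labelings of
#' the same cells.
#'
#' @param labels_a,labels_b vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}

#' Mean per-cell and per-gene Pearson correlation
#'
#' Correlates each cell's (row) and each gene's (column) profile between a
#' reference matrix (e.g. counts without dropout) and an imputed matrix,
#' then averages.  A constant row or column has undefined correlation and
#' contributes 0 with a warning.
#'
#' @param truth reference matrix or `count_matrix`.
#' @param imputed numeric matrix of the same shape (or `zinb_imputed`).
#' @return named numeric vector `c(rho_cell=, rho_gene=)`.
#' @export
cell_gene_correlation <- function(truth, imputed) {
  if (inherits(truth, "count_matrix")) truth <- truth$counts
  if (inherits(imputed, "zinb_imputed")) imputed <- imputed$values
  truth <- as.matrix(truth); imputed <- as.matrix(imputed)
  if (!all(dim(truth) == dim(imputed))) stop("shape mismatch")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  rc <- vapply(seq_len(nrow(truth)), function(i) safe_cor(truth[i, ], imputed[i, ]),
               numeric(1))
  rg <- vapply(seq_len(ncol(truth)), function(j) safe_cor(truth[, j], imputed[, j]),
               numeric(1))
  n_const <- sum(is.na(rc)) + sum(is.na(rg))
  if (n_const > 0) {
    warning(sprintf("%d constant row(s)/column(s) contribute 0 to the correlation", n_const))
    rc[is.na(rc)] <- 0
    rg[is.na(rg)] <- 0
  }
  c(rho_cell = mean(rc), rho_gene = mean(rg))
}
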