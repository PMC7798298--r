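#' Number of free parameters of the mixture
#'
#' Counts the independently optimized quantities: `K - 1` free mixing
#' weights, and per (gene, cluster) a component simplex with `L - 1` free
#' entries plus an \eqn{(\alpha, \beta)} pair for each NB component (`L - 1`
#' NB components when a dropout term is present, one when `L = 1`).
#'
#' @param K,G,L model dimensions (all >= 1).
#' @return integer parameter count.
#' @examples
#' count_free_params(2, 2, 2)  # 13
#' @export
count_free_params <- function(K, G, L) {
  stopifnot(K >= 1, G >= 1, L >= 1)
  n_nb <- max(L - 1, 1)
  (K - 1) + K * G * ((L - 1) + 2 * n_nb)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2P - 2 loglik`; `BIC = P log(C) - 2 loglik` with `C` the number of
#' cells.
#'
#' @param loglik maximized dataset log likelihood.
#' @param P free-parameter count (see [count_free_params()]).
#' @param C number of cells.
#' @return named numeric vector with elements `AIC` and `BIC`.
#' @export
information_criteria <- function(loglik, P, C) {
  stopifnot(C >= 1)
  c(AIC = 2 * P - 2 * loglik, BIC = P * log(C) - 2 * loglik)
}

#' Select the number of cell types by AIC or BIC
#'
#' Fits the model for each candidate `K` with multi-restart EM, keeps the
#' best log likelihood per `K`, and returns the `K` minimizing the chosen
#' criterion (ties broken toward smaller `K`).
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param K_range integer vector of candidate cluster numbers.
#' @param L components per gene.
#' @param restarts_per_K random restarts per candidate `K`.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param seed integer seed.
#' @param ... passed to [multi_restart_fit()] (e.g. `scalers`, `max_iter`).
#' @return list with `K_best`, `table` (data.frame: K, loglik, P, AIC, BIC,
#'   init), and `fits` (best fit per K).
#' @export
select_num_clusters <- function(counts, K_range = 1:5, L = 2,
                                restarts_per_K = 10,
                                criterion = c("AIC", "BIC"), seed = 1L, ...) {
  criterion <- match.arg(criterion)
  if (length(K_range) == 0) stop("K_range must be nonempty")
  K_range <- sort(unique(as.integer(K_range)))
  counts <- as_count_matrix(counts)
  C <- nrow(counts$counts); G <- ncol(counts$counts)
  fits <- list()
  rows <- list()
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- multi_restart_fit(counts, K, L,
                             n_random_restarts = restarts_per_K,
                             seed = child_seed(seed, K), ...)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(K = K, loglik = fit$loglik, P = fit$n_params,
                            AIC = fit$AIC, BIC = fit$BIC,
                            init = fit$init_condition)
  }
  tab <- do.call(rbind, rows)
  K_best <- tab$K[which.min(tab[[criterion]])]  # K sorted: ties go to smaller K
  list(K_best = K_best, table = tab, fits = fits)
}

#' Write a model-selection table as TSV
#'
#' @param table the `table` element returned by [select_num_clusters()].
#' @param path output file path.
#' @export
write_selection_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
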