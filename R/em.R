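#' E-step: posterior responsibilities
#'
#' Computes the cluster posteriors \eqn{\gamma_{c,k} = p(k \mid x_c)} (softmax
#' of the per-cell log joints) and the per-entry component posteriors
#' \eqn{p(l \mid k, x_{c,g})}.  The dropout component has posterior zero
#' wherever the observed count is positive.
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param params [zinb_params()].
#' @param scalers per-cell scalers (`NULL` = unit).
#' @return list with `gamma` (C x K), `comp_post` (C x G x K x L array),
#'   `loglik` (scalar dataset log likelihood), `log_joint` (C x K).
#' @export
e_step <- function(counts, params, scalers = NULL) {
  counts <- as_count_matrix(counts)
  validate_params(params)
  X <- counts$counts
  C <- nrow(X); G <- ncol(X); K <- params$K; L <- params$L
  s <- expand_scalers(scalers, C)
  comp_post <- array(0, c(C, G, K, L))
  logf <- array(NA_real_, c(C, G, K))
  for (k in seq_len(K)) {
    for (g in seq_len(G)) {
      terms <- component_log_terms(X[, g], g, k, params, s)  # C x L
      lf <- logsumexp_rows(terms)
      logf[, g, k] <- lf
      comp_post[, g, k, ] <- exp(terms - lf)
    }
  }
  per_gene_sum <- vapply(seq_len(K), function(k) rowSums(logf[, , k, drop = FALSE]),
                         numeric(C))
  per_gene_sum <- matrix(per_gene_sum, C, K)  # vapply drops dim when C = 1
  log_joint <- sweep(per_gene_sum, 2, log(params$pi), "+")
  total <- logsumexp_rows(log_joint)
  if (any(!is.finite(total))) {
    cbad <- which(!is.finite(total))[1]
    gbad <- which(!is.finite(logf[cbad, , 1]))[1] %||% NA
    stop(sprintf("non-finite likelihood at cell '%s' (gene %s)",
                 counts$cell_ids[cbad], gbad))
  }
  gamma <- softmax_rows(log_joint)
  list(gamma = gamma, comp_post = comp_post, loglik = sum(total),
       log_joint = log_joint)
}

# collapse (x, s, weight) triples over cells with identical (x, s) pairs;
# shrinks the weighted NB objective from C terms to the number of distinct
# count values when scalers are constant
aggregate_weighted_counts <- function(x, w, s) {
  if (length(unique(s)) == 1L) {
    tab <- rowsum(w, group = x)
    xs <- as.numeric(rownames(tab))
    list(x = xs, w = as.numeric(tab), s = rep(s[1], length(xs)))
  } else {
    list(x = x, w = w, s = s)
  }
}

# weighted NB maximum likelihood for one (gene, cluster, component):
# maximize sum_c w_c * nb_log_pmf(x_c, alpha, beta, s_c) over log(alpha),
# log(beta) by BFGS with analytic gradient, warm-started at (alpha0, beta0)
weighted_nb_mle <- function(x, w, s, alpha0, beta0, maxit = 25) {
  keep <- w > 0
  x <- x[keep]; w <- w[keep]; s <- s[keep]
  if (length(x) == 0 || sum(w) < 1e-10) {
    return(list(alpha = alpha0, beta = beta0, ok = FALSE))
  }
  ag <- aggregate_weighted_counts(x, w, s)
  x <- ag$x; w <- ag$w; s <- ag$s
  nll <- function(par) {
    a <- clip(exp(par[1]), .ALPHA_MIN, .ALPHA_MAX)
    b <- clip(exp(par[2]), .ALPHA_MIN, .ALPHA_MAX)
    -sum(w * (lgamma(x + a) - lgamma(a) + a * log(b / (b + s)) +
                x * log(s / (b + s))))
  }
  gr <- function(par) {
    a <- clip(exp(par[1]), .ALPHA_MIN, .ALPHA_MAX)
    b <- clip(exp(par[2]), .ALPHA_MIN, .ALPHA_MAX)
    da <- sum(w * (digamma(x + a) - digamma(a) + log(b / (b + s))))
    db <- sum(w * (a / b - (a + x) / (b + s)))
    c(-a * da, -b * db)
  }
  start <- log(clip(c(alpha0, beta0), .ALPHA_MIN, .ALPHA_MAX))
  fit <- tryCatch(
    stats::optim(start, nll, gr, method = "BFGS",
                 control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value > nll(start)) {
    # optimizer failure: keep the previous values
    return(list(alpha = alpha0, beta = beta0, ok = FALSE))
  }
  list(alpha = clip(exp(fit$par[1]), .ALPHA_MIN, .ALPHA_MAX),
       beta = clip(exp(fit$par[2]), .ALPHA_MIN, .ALPHA_MAX),
       ok = TRUE)
}

#' M-step: parameter updates given responsibilities
#'
#' Closed-form updates for the mixing weights and component weights, and a
#' bounded quasi-Newton maximization (in log-parameter space, warm-started
#' from the current values) of the responsibility-weighted NB log likelihood
#' for each \eqn{(\alpha, \beta)} pair.
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param resp responsibilities from [e_step()].
#' @param params current [zinb_params()] (warm start).
#' @param scalers per-cell scalers.
#' @param inner_maxit maximum quasi-Newton iterations per (gene, cluster,
#'   component); default 25.
#' @return updated [zinb_params()].
#' @export
m_step <- function(counts, resp, params, scalers = NULL, inner_maxit = 25) {
  counts <- as_count_matrix(counts)
  X <- counts$counts
  C <- nrow(X); G <- ncol(X); K <- params$K; L <- params$L
  s <- expand_scalers(scalers, C)
  gamma <- pmax(resp$gamma, 1e-12)  # responsibility floor avoids 0/0
  new <- params
  new$pi <- colSums(gamma) / sum(gamma)
  cluster_mass <- colSums(gamma)                     # length K
  l0 <- as.integer(params$dropout)
  n_fail <- 0L
  for (k in seq_len(K)) {
    for (g in seq_len(G)) {
      r_gl <- gamma[, k] * resp$comp_post[, g, k, ]   # C x L
      if (L == 1) r_gl <- matrix(r_gl, ncol = 1)
      new$q[g, k, ] <- colSums(r_gl) / cluster_mass[k]
      for (j in seq_len(params$n_nb)) {
        r <- r_gl[, l0 + j]
        if (sum(r) < 1e-8) next  # degenerate: no mass on this component
        mle <- weighted_nb_mle(X[, g], r, s,
                               params$alpha[g, k, j], params$beta[g, k, j],
                               maxit = inner_maxit)
        if (!mle$ok) n_fail <- n_fail + 1L
        new$alpha[g, k, j] <- mle$alpha
        new$beta[g, k, j] <- mle$beta
      }
    }
  }
  if (n_fail > 0) warning(sprintf("%d NB component update(s) kept previous values", n_fail))
  sanitize_params(new)
}

#' Fit the mixture by expectation-maximization
#'
#' Alternates [e_step()] and [m_step()] until the relative change in dataset
#' log likelihood falls below `tol` *and* the maximum relative parameter
#' change falls below `param_tol` (dual criterion), or `max_iter` is reached.
#'
#' Scalers default to 1 for every cell (appropriate for simulated data
#' generated with unit scalers); pass [compute_cell_scalers()] output for
#' library-size normalization of real data.
#'
#' @param counts `count_matrix` or coercible matrix.
#' @param K number of clusters (cell types).
#' @param L components per gene (2 = dropout + one NB; 1 = plain NB).
#' @param init either a [zinb_params()] object used as the starting point,
#'   or an [init_strategy()]; default random initialization.
#' @param tol relative log-likelihood convergence tolerance.
#' @param param_tol maximum relative parameter change at convergence.
#' @param max_iter maximum EM iterations.
#' @param seed integer seed used when the initialization is stochastic.
#' @param scalers per-cell scalers (`NULL` = unit).
#' @param inner_maxit passed to [m_step()].
#' @return object of class `zinb_fit`: `params`, `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `gamma` (final responsibilities), `seed`,
#'   `init_condition`, `n_params`, `AIC`, `BIC`.
#' @export
fit_em <- function(counts, K, L = 2, init = init_strategy("random"),
                   tol = 1e-6, param_tol = 1e-2, max_iter = 200,
                   seed = 1L, scalers = NULL, inner_maxit = 25) {
  counts <- as_count_matrix(counts)
  stopifnot(K >= 1, L >= 1, max_iter >= 1)
  if (inherits(init, "zinb_params")) {
    params <- sanitize_params(init)
    init_label <- "params"
  } else {
    params <- initialize_params(counts, K, L, init, scalers = scalers)
    init_label <- paste(init$method, init$transform, sep = "+")
  }
  if (params$K != K || params$L != L) stop("init parameters do not match K, L")
  trace <- numeric(0)
  converged <- FALSE
  prev_dpar <- Inf
  for (i in seq_len(max_iter)) {
    es <- e_step(counts, params, scalers)
    trace[i] <- es$loglik
    if (i > 1) {
      rel_ll <- abs(trace[i] - trace[i - 1]) / (abs(trace[i - 1]) + 1e-12)
      if (rel_ll < tol && prev_dpar < param_tol) {
        converged <- TRUE
        break
      }
    }
    if (i == max_iter) break
    newp <- m_step(counts, es, params, scalers, inner_maxit = inner_maxit)
    prev_dpar <- param_rel_change(params, newp)
    params <- newp
  }
  P <- count_free_params(K, ncol(counts$counts), L)
  ll <- trace[length(trace)]
  ic <- information_criteria(ll, P, nrow(counts$counts))
  structure(list(params = params, loglik = ll, loglik_trace = trace,
                 n_iter = length(trace), converged = converged,
                 gamma = es$gamma, seed = seed, init_condition = init_label,
                 n_params = P, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
                 scalers = scalers),
            class = "zinb_fit")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf("zinb_fit: K=%d, L=%d | loglik %.2f after %d iterations (%s)\n",
              x$params$K, x$params$L, x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("AIC %.2f | BIC %.2f | init %s\n", x$AIC, x$BIC, x$init_condition))
  invisible(x)
}

#' Multi-restart EM
#'
#' Runs [fit_em()] from several initializations (explicit strategies and/or
#' purely random restarts) and keeps the fit with the highest final log
#' likelihood.
#'
#' @inheritParams fit_em
#' @param strategies list of [init_strategy()] objects (may be `NULL`).
#' @param n_random_restarts number of additional random initializations.
#' @return the winning `zinb_fit`, with an extra element
#'   `candidate_logliks` recording every restart's final log likelihood.
#' @export
multi_restart_fit <- function(counts, K, L = 2, strategies = NULL,
                              n_random_restarts = 0, tol = 1e-6,
                              max_iter = 200, seed = 1L, scalers = NULL, ...) {
  strategies <- strategies %||% list()
  if (n_random_restarts > 0) {
    strategies <- c(strategies, lapply(seq_len(n_random_restarts), function(i)
      init_strategy("random", seed = child_seed(seed, i))))
  }
  if (length(strategies) == 0) stop("need at least one strategy or restart")
  fits <- list()
  for (i in seq_along(strategies)) {
    fits[[i]] <- tryCatch(
      fit_em(counts, K, L, init = strategies[[i]], tol = tol,
             max_iter = max_iter, seed = strategies[[i]]$seed %||% seed,
             scalers = scalers, ...),
      error = function(e) e)
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("all restarts failed; first error: ",
                     conditionMessage(fits[[1]]))
  lls <- vapply(fits[ok], function(f) f$loglik, numeric(1))
  best <- fits[ok][[which.max(lls)]]
  best$candidate_logliks <- lls
  best
}
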