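# Dirichlet-multinomial mixture (DMM) community clustering with
# Laplace-approximation model selection.

logsumexp_rows <- function(L) {
  mx <- apply(L, 1, max)
  mx + log(rowSums(exp(L - mx)))
}

dm_component_loglik <- function(X, alpha, n_i) {
  # per-sample DM log-likelihood (without the multinomial coefficient)
  A <- sum(alpha)
  lgamma(A) - lgamma(A + n_i) +
    rowSums(lgamma(sweep(X, 2, alpha, `+`))) - sum(lgamma(alpha))
}

dmm_em <- function(X, K, max_iter, tol, min_alpha = 1e-6) {
  n <- nrow(X); t_n <- ncol(X)
  n_i <- rowSums(X)
  # random hard init softened
  lab <- sample.int(K, n, replace = TRUE)
  r <- matrix(0.05 / max(K - 1, 1), n, K)
  r[cbind(seq_len(n), lab)] <- if (K == 1) 1 else 0.95
  alpha <- matrix(0, K, t_n)
  props <- (X + 0.5) / (n_i + 0.5 * t_n)
  for (k in seq_len(K)) {
    alpha[k, ] <- pmax(colSums(r[, k] * props) / sum(r[, k]), 1e-4) * 10
  }
  pi_k <- colMeans(r)
  ll_trace <- numeric(0)
  const <- sum(lgamma(n_i + 1)) - sum(lgamma(X + 1))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # M step (skip on first pass: init responsibilities already set)
    pi_k <- pmax(colMeans(r), 1e-10)
    for (k in seq_len(K)) {
      rk <- r[, k]
      for (inner in 1:3) {
        A <- sum(alpha[k, ])
        num <- colSums(rk * (digamma(sweep(X, 2, alpha[k, ], `+`)))) -
          sum(rk) * digamma(alpha[k, ])
        den <- sum(rk * (digamma(A + n_i) - digamma(A)))
        alpha[k, ] <- pmax(alpha[k, ] * num / den, min_alpha)
      }
    }
    # E step
    L <- vapply(seq_len(K), function(k) {
      log(pi_k[k]) + dm_component_loglik(X, alpha[k, ], n_i)
    }, numeric(n))
    L <- matrix(L, n, K)
    lse <- logsumexp_rows(L)
    r <- exp(L - lse)
    ll <- sum(lse) + const
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(alpha = alpha, pi = pi_k, r = r, loglik = ll, trace = ll_trace)
}

dmm_laplace <- function(X, fit, tau = 3) {
  # Negative log model evidence by Laplace approximation: fit term, log
  # prior at the optimum, and half log-determinant of the Hessian in the
  # log-alpha parameterization (scale-free; at an interior optimum
  # H_log = diag(a) H diag(a)). Each component Hessian is diagonal plus
  # rank-one, so its log-determinant follows from the matrix determinant
  # lemma; the Gaussian volume factors of the Laplace integral cancel
  # against the diffuse N(0, tau^2) prior on log alpha up to log(tau) per
  # parameter. Mixture weights carry a uniform (Dirichlet(1)) prior and an
  # O(n)-curvature Laplace block. A non-positive-definite alpha block marks
  # a degenerate optimum where the approximation is invalid.
  K <- nrow(fit$alpha); t_n <- ncol(fit$alpha)
  n <- nrow(X)
  n_i <- rowSums(X)
  logdet <- 0; quad <- 0; p <- 0
  for (k in seq_len(K)) {
    rk <- fit$r[, k]
    a <- fit$alpha[k, ]
    A <- sum(a)
    d <- colSums(rk * (-trigamma(sweep(X, 2, a, `+`)))) + sum(rk) * trigamma(a)
    cc <- sum(rk * (trigamma(A + n_i) - trigamma(A)))
    # taxa effectively absent from the component sit at the alpha -> 0
    # boundary (no diagonal curvature); they are not free parameters of
    # this optimum and are left out of the Laplace integral
    act <- d > 1e-8
    if (!any(act)) return(NA_real_)
    lemma <- 1 + cc * sum(1 / d[act])
    if (lemma <= 0) return(NA_real_)
    logdet <- logdet + sum(log(d[act])) + log(lemma) + 2 * sum(log(a[act]))
    quad <- quad + sum(log(a[act])^2) / (2 * tau^2)
    p <- p + sum(act)
  }
  -fit$loglik + 0.5 * logdet + p * log(tau) + quad +
    0.5 * (K - 1) * log(n) - lgamma(K)
}

#' Fit a Dirichlet-multinomial mixture
#'
#' EM over Dirichlet-multinomial components (log-Beta-function form), with
#' the component Dirichlet parameters updated by weighted fixed-point
#' iterations; the best of `n_init` random initialisations is kept. Hard
#' labels are the argmax responsibilities.
#'
#' @param counts Wide count table or matrix of non-negative integers. By
#'   default the raw counts are modelled (a multinomial likelihood needs
#'   counts); `input = "clr_literal"` instead rounds min-shifted CLR scores
#'   to pseudo-counts -- provided for comparability, and discouraged.
#' @param k Number of mixture components (`1 <= k <= n`).
#' @param n_init Random restarts.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param seed Seed for the restarts (mandatory).
#' @param input `"counts"` or `"clr_literal"`.
#' @return A `microfam_dmm`: `k`, `weights`, `alpha` (component x taxon),
#'   `responsibilities`, `assignments` tibble (`sample_id`, `cluster`,
#'   `max_responsibility`), `log_likelihood`, `ll_trace`,
#'   `laplace_evidence` (negative log evidence; lower is better).
#' @export
fit_dmm <- function(counts, k, n_init = 5, max_iter = 200, tol = 1e-8,
                    seed, input = c("counts", "clr_literal")) {
  input <- match.arg(input)
  if (missing(seed)) abort("`seed` is mandatory.")
  X <- count_matrix(counts, require_integer = (input == "counts"))
  if (input == "clr_literal") {
    cm <- value_matrix(clr_transform(X))
    X <- round((cm - min(cm)) * 2)
  }
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(X)) abort("`k` cannot exceed the number of samples.")
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- dmm_em(X, k, max_iter, tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  if (min(colSums(best$r)) < 2) {
    warn(sprintf(
      "a mixture component collapsed (effective size %.2f): K = %d is likely too large; evidence set to NA.",
      min(colSums(best$r)), k))
    lap <- NA_real_
  } else {
    lap <- dmm_laplace(X, best)
    if (is.na(lap)) {
      warn(sprintf("degenerate optimum at K = %d: Laplace approximation invalid; evidence set to NA.", k))
    }
  }
  cl <- max.col(best$r)
  structure(list(
    k = k, weights = best$pi,
    alpha = structure(best$alpha, dimnames = list(NULL, colnames(X))),
    responsibilities = best$r,
    assignments = tibble::tibble(sample_id = rownames(X), cluster = cl,
                                 max_responsibility = best$r[cbind(seq_len(nrow(X)), cl)]),
    log_likelihood = best$loglik, ll_trace = best$trace,
    laplace_evidence = lap
  ), class = "microfam_dmm")
}

#' @export
print.microfam_dmm <- function(x, ...) {
  cat("<microfam_dmm> K =", x$k,
      " logLik =", signif(x$log_likelihood, 8),
      " Laplace(-log evidence) =", signif(x$laplace_evidence, 8), "\n")
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' Select the number of DMM community clusters
#'
#' Fits a DMM for each candidate K and picks the minimum of the
#' Laplace-approximate negative log evidence. The conventional search range
#' is 1-15 clusters.
#'
#' @param counts Wide count table or matrix.
#' @param k_range Candidate component counts (default `1:15`).
#' @param seed Seed (mandatory).
#' @inheritParams fit_dmm
#' @return A `microfam_dmm_selection`: `best_k`, `trace` tibble
#'   (`k`, `laplace`, `log_likelihood`), and `best_fit`. Ks that fail to
#'   converge are skipped with a warning and recorded as `NA` in the trace.
#' @export
select_n_clusters <- function(counts, k_range = 1:15, n_init = 5,
                              max_iter = 200, tol = 1e-8, seed,
                              input = c("counts", "clr_literal")) {
  if (missing(seed)) abort("`seed` is mandatory.")
  input <- match.arg(input)
  X <- count_matrix(counts)
  if (max(k_range) > nrow(X)) abort("`k_range` cannot exceed the number of samples.")
  fits <- vector("list", length(k_range))
  lap <- ll <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    fits[i] <- list(tryCatch(
      suppressWarnings(
        fit_dmm(counts, k_range[i], n_init = n_init, max_iter = max_iter,
                tol = tol, seed = seed + i, input = input)),
      error = function(e) {
        warn(sprintf("K = %d failed (%s); skipped.", k_range[i], conditionMessage(e)))
        NULL
      }))
    if (!is.null(fits[[i]])) {
      lap[i] <- fits[[i]]$laplace_evidence
      ll[i] <- fits[[i]]$log_likelihood
      if (is.na(lap[i])) {
        warn(sprintf("K = %d reached a degenerate optimum; skipped in the evidence trace.",
                     k_range[i]))
      }
    }
  }
  if (all(is.na(lap))) abort("no candidate K produced a valid evidence value.")
  best <- which.min(lap)
  structure(list(
    best_k = k_range[best],
    trace = tibble::tibble(k = k_range, laplace = lap, log_likelihood = ll),
    best_fit = fits[[best]]
  ), class = "microfam_dmm_selection")
}

#' @export
print.microfam_dmm_selection <- function(x, ...) {
  cat("<microfam_dmm_selection> best K =", x$best_k, "\n")
  print(as.data.frame(x$trace))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Cluster label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
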