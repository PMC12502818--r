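# Distance-based permutation ANOVA (McArdle-Anderson partition) with
# optional conditioning, and the multivariate homogeneity-of-dispersions
# test.

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = q$rank)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a distance matrix by the sequential (Type I) terms of a model
#' formula using the McArdle-Anderson decomposition: with
#' `G = -1/2 J D^2 J` the Gower-centred inner-product matrix, each term's
#' sum of squares is `tr((H_k - H_{k-1}) G)` for the growing hat matrices
#' `H_k`, and pseudo-F compares term mean squares to the residual mean
#' square. Significance is assessed by permuting samples; with conditioning
#' terms, permutation follows the Freedman-Lane scheme (residuals of the
#' reduced, condition-only model are permuted while the fitted conditioning
#' structure is retained).
#'
#' @param d A `microfam_dist`, `dist` object or symmetric distance matrix.
#' @param metadata Data frame with one row per sample; if it has a
#'   `sample_id` column, rows are matched to the distance ids, otherwise
#'   row order must match.
#' @param formula One-sided formula of sequential model terms, e.g.
#'   `~ age + diagnosis`.
#' @param condition Optional one-sided formula of conditioning terms fitted
#'   before all model terms (their SS is reported but not tested).
#' @param n_perm Number of permutations (the study convention is 10000;
#'   default here 999 for interactive use).
#' @param seed Optional seed for the permutation stream.
#' @return A `microfam_permanova` with a `terms` tibble (`term`, `df`,
#'   `sum_of_squares`, `pseudo_F`, `R2`, `p_perm`), residual/total rows,
#'   and the overall `adj_R2`. `tidy()` and `glance()` methods apply.
#' @export
permanova <- function(d, metadata, formula, condition = NULL,
                      n_perm = 999, seed = NULL) {
  dm <- if (inherits(d, "microfam_dist")) d$values else as.matrix(d)
  n <- nrow(dm)
  ids <- rownames(dm)
  if (!is.null(ids) && "sample_id" %in% names(metadata)) {
    idx <- match(ids, metadata$sample_id)
    if (anyNA(idx)) abort("metadata is missing rows for some samples in `d`.")
    metadata <- metadata[idx, , drop = FALSE]
  } else if (nrow(metadata) != n) {
    abort("metadata rows must match the distance matrix.")
  }

  G <- gower_center(dm)
  tt <- terms(formula)
  mf <- model.frame(delete.response(tt), metadata, na.action = na.omit)
  if (nrow(mf) != n) abort("metadata is incomplete for the design terms.")
  X <- model.matrix(delete.response(tt), mf)
  asgn <- attr(X, "assign")
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0) abort("the formula must contain at least one term.")

  Z <- matrix(1, n, 1)
  cond_df <- 0
  if (!is.null(condition)) {
    Zc <- model.matrix(condition, metadata)
    Z <- cbind(Z, Zc[, -1, drop = FALSE])
    cond_df <- hat_matrix(Z)$rank - 1
  }

  # growing hat matrices: conditioning first, then each sequential term
  hats <- vector("list", length(labels) + 1)
  hats[[1]] <- hat_matrix(Z)
  Xcur <- Z
  for (k in seq_along(labels)) {
    Xcur <- cbind(Xcur, X[, asgn == k, drop = FALSE])
    hats[[k + 1]] <- hat_matrix(Xcur)
  }
  full <- hats[[length(hats)]]
  if (full$rank < hats[[1]]$rank + sum(vapply(seq_along(labels), function(k) {
    qr(X[, asgn == k, drop = FALSE])$rank
  }, 0))) {
    ranks <- vapply(seq_along(hats), function(i) hats[[i]]$rank, 0)
    aliased <- labels[which(diff(ranks) == 0)]
    abort(paste("rank-deficient design; aliased term(s):",
                paste(aliased, collapse = ", ")))
  }

  dH <- lapply(seq_along(labels), function(k) hats[[k + 1]]$H - hats[[k]]$H)
  df_term <- vapply(seq_along(labels), function(k) {
    hats[[k + 1]]$rank - hats[[k]]$rank
  }, 0)
  df_res <- n - full$rank
  if (df_res <= 0) abort("no residual degrees of freedom.")

  ss_total <- sum(diag(G))
  ss_cond <- sum(hats[[1]]$H * G) # includes the (zero) intercept part
  ss_term <- vapply(dH, function(h) sum(h * G), 0)
  ss_res <- ss_total - ss_cond - sum(ss_term)
  f_obs <- (ss_term / df_term) / (ss_res / df_res)

  # Freedman-Lane: permute the reduced-model residual G
  Rz <- diag(n) - hats[[1]]$H
  Gr <- Rz %*% G %*% Rz
  perm_stat <- function(p) {
    Gp <- Gr[p, p]
    st <- vapply(dH, function(h) sum(h * Gp), 0)
    sr <- sum(diag(Gp)) - sum(hats[[1]]$H * Gp) - sum(st)
    (st / df_term) / (sr / df_res)
  }
  run_perms <- function() {
    exceed <- numeric(length(labels))
    for (i in seq_len(n_perm)) {
      fp <- perm_stat(sample.int(n))
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
    exceed
  }
  exceed <- if (is.null(seed)) run_perms() else with_seed(seed, run_perms())
  p_perm <- (exceed + 1) / (n_perm + 1)

  r2 <- ss_term / ss_total
  df_model <- sum(df_term)
  r2_model <- sum(ss_term) / (ss_total - ss_cond)
  adj_r2 <- 1 - (1 - r2_model) * (n - 1 - cond_df) / (n - 1 - cond_df - df_model)

  terms_tbl <- tibble::tibble(
    term = c(labels, "Residual", "Total"),
    df = c(df_term, df_res, n - 1),
    sum_of_squares = c(ss_term, ss_res, ss_total),
    pseudo_F = c(f_obs, NA, NA),
    R2 = c(r2, ss_res / ss_total, 1),
    p_perm = c(p_perm, NA, NA)
  )
  structure(list(terms = terms_tbl, adj_R2 = adj_r2, n_perm = n_perm,
                 n = n, condition_df = cond_df, ss_condition = ss_cond,
                 label = "distance-based permutation ANOVA (PERMANOVA)"),
            class = "microfam_permanova")
}

gower_center <- function(dm) {
  A <- -0.5 * dm^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' @export
print.microfam_permanova <- function(x, ...) {
  cat("<microfam_permanova> n =", x$n, ", permutations =", x$n_perm, "\n")
  print(as.data.frame(x$terms))
  cat("overall adj. R2:", signif(x$adj_R2, 4), "\n")
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' Tests equality of multivariate spread across groups: samples are
#' embedded by PCoA (with the standard treatment of negative eigenvalues),
#' each sample's distance to its own group centroid is computed, and a
#' one-way F on those distances is assessed by permutation (vegan's
#' `betadisper`/`permutest` machinery).
#'
#' @param d A `microfam_dist`, `dist` or symmetric matrix.
#' @param groups Grouping factor aligned with the samples of `d`.
#' @param n_perm Number of permutations.
#' @param seed Optional permutation seed.
#' @return A `microfam_dispersion`: tibble `distances` (`sample_id`,
#'   `group`, `distance_to_centroid`), observed `F`, and `p_perm`. Groups
#'   of size 1 are excluded with a warning.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = NULL) {
  dm <- if (inherits(d, "microfam_dist")) d$values else as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(dm)) abort("`groups` must match the samples of `d`.")
  small <- names(which(table(groups) < 2))
  if (length(small) > 0) {
    warn(paste("excluding group(s) of size 1:", paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    dm <- dm[keep, keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) abort("need at least two groups with >= 2 samples.")
  bd <- vegan::betadisper(as.dist(dm), groups, type = "centroid")
  run <- function() vegan::permutest(bd, permutations = n_perm)
  pt <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(
    distances = tibble::tibble(
      sample_id = rownames(dm) %||% paste0("S", seq_len(nrow(dm))),
      group = groups,
      distance_to_centroid = unname(bd$distances)
    ),
    F = unname(pt$tab$F[1]),
    p_perm = unname(pt$tab[1, "Pr(>F)"]),
    n_perm = n_perm
  ), class = "microfam_dispersion")
}

#' @export
print.microfam_dispersion <- function(x, ...) {
  cat("<microfam_dispersion> F =", signif(x$F, 5),
      ", permutation p =", signif(x$p_perm, 4), "\n")
  invisible(x)
}
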