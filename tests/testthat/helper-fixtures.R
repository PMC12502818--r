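# Shared fixtures and independent oracles used across the suite.

# small deterministic count table: 4 samples x 5 taxa
toy_counts <- function() {
  m <- matrix(c(
    10, 0, 3, 7, 1,
    20, 0, 6, 14, 2,
    5, 2, 1, 0, 12,
    8, 1, 4, 2, 6
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("S", 1:4), paste0("T", 1:5)))
  count_tbl(m)
}

# one trio pedigree
trio_pedigree <- function() {
  tibble::tibble(
    subject_id = c("F", "M", "C"),
    father_id = c(NA, NA, "F"),
    mother_id = c(NA, NA, "M"),
    sex = c("M", "F", "F"),
    family_id = "FAM1"
  )
}

# brute-force induced-subgraph graphlet counter (oracle)
brute_graphlets <- function(A) {
  n <- nrow(A)
  cnt <- setNames(numeric(9), paste0("G", 0:8))
  cnt["G0"] <- sum(A) / 2
  if (n >= 3) {
    for (cmb in combn(n, 3, simplify = FALSE)) {
      e <- sum(A[cmb, cmb]) / 2
      if (e == 2) cnt["G1"] <- cnt["G1"] + 1
      if (e == 3) cnt["G2"] <- cnt["G2"] + 1
    }
  }
  if (n >= 4) {
    for (cmb in combn(n, 4, simplify = FALSE)) {
      S <- A[cmb, cmb]; e <- sum(S) / 2; dg <- rowSums(S)
      if (e == 3 && max(dg) == 2 && min(dg) > 0) cnt["G3"] <- cnt["G3"] + 1
      if (e == 3 && max(dg) == 3) cnt["G4"] <- cnt["G4"] + 1
      if (e == 4 && max(dg) == 2) cnt["G5"] <- cnt["G5"] + 1
      if (e == 4 && max(dg) == 3 && min(dg) == 1) cnt["G6"] <- cnt["G6"] + 1
      if (e == 5) cnt["G7"] <- cnt["G7"] + 1
      if (e == 6) cnt["G8"] <- cnt["G8"] + 1
    }
  }
  cnt
}

random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, p)
  A <- A + t(A)
  dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  A
}

graph_of <- function(A) igraph::graph_from_adjacency_matrix(A, "undirected")

# draw a pure Dirichlet-multinomial mixture (oracle-side generator)
draw_dm_mixture <- function(alphas, labels, depth = 5000) {
  t_n <- length(alphas[[1]])
  X <- t(vapply(labels, function(l) {
    p <- rgamma(t_n, alphas[[l]])
    p <- p / sum(p)
    rmultinom(1, depth, p)[, 1]
  }, numeric(t_n)))
  rownames(X) <- paste0("S", seq_along(labels))
  X
}

# direct single-component Dirichlet-multinomial MLE (oracle for K = 1)
dm_mle_oracle <- function(X) {
  n_i <- rowSums(X)
  negll <- function(la) {
    a <- exp(la)
    A <- sum(a)
    -(sum(lgamma(A) - lgamma(A + n_i)) +
        sum(lgamma(sweep(X, 2, a, `+`))) - nrow(X) * sum(lgamma(a)))
  }
  init <- log(pmax(colMeans(X / n_i), 1e-6) * 10)
  fit <- optim(init, negll, method = "L-BFGS-B", lower = -12, upper = 12,
               control = list(maxit = 1000, factr = 1e3))
  exp(fit$par)
}

# full-matrix REML likelihood oracle: profile REML over the variance
# ratio with dense solves (no eigen-rotation shortcut)
reml_oracle_h2 <- function(y, X, A) {
  n <- length(y); p <- ncol(X)
  prof <- function(lg) {
    g <- exp(lg)
    V <- g * A + diag(n)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(list(ll = -Inf))
    Vi <- chol2inv(cV)
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    rss <- drop(t(r) %*% Vi %*% r)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + 2 * sum(log(diag(cV))) +
                    as.numeric(determinant(XtViX)$modulus) + (n - p))
    list(ll = ll, s2 = s2, g = g)
  }
  opt <- optimize(function(lg) prof(lg)$ll, c(-14, 14), maximum = TRUE,
                  tol = 1e-10)
  at <- prof(opt$maximum)
  sg2 <- at$g * at$s2; se2 <- at$s2
  list(h2 = sg2 / (sg2 + se2), sigma_g2 = sg2, sigma_e2 = se2,
       loglik = at$ll)
}
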