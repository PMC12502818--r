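# Pedigree-based kinship and single-random-effect REML heritability.

#' Additive relationship matrix from a pedigree
#'
#' Computes kinship coefficients Phi by the standard recursive tabular
#' method (founders down, parents before children) and returns the additive
#' relationship matrix `A = 2 Phi`. Subjects without recorded relatives get
#' identity rows; inbreeding shows up on the diagonal (`1 + F`).
#'
#' @param pedigree Data frame with `subject_id`, `father_id`, `mother_id`
#'   (`NA` or `""` for founders); extra columns are ignored.
#' @return A `microfam_kinship`: `matrix` (A, symmetric PSD) and
#'   `subject_ids`.
#' @export
kinship_matrix <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  need <- c("subject_id", "father_id", "mother_id")
  if (!all(need %in% names(ped))) abort("pedigree needs subject/father/mother ids.")
  ids <- as.character(ped$subject_id)
  if (anyDuplicated(ids)) abort("duplicate subject ids in pedigree.")
  fa <- as.character(ped$father_id); mo <- as.character(ped$mother_id)
  fa[fa %in% c("", "NA")] <- NA; mo[mo %in% c("", "NA")] <- NA
  bad <- setdiff(na.omit(c(fa, mo)), ids)
  if (length(bad) > 0) {
    abort(paste("parent id(s) missing from the pedigree:", paste(bad, collapse = ", ")))
  }
  n <- length(ids)
  fi <- match(fa, ids); mi <- match(mo, ids)

  # topological depth; failure to settle indicates a cycle
  depth <- ifelse(is.na(fi) & is.na(mi), 0L, NA_integer_)
  for (pass in seq_len(n)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    for (i in todo) {
      dp <- c(depth[fi[i]], depth[mi[i]])
      dp <- dp[!is.na(c(fi[i], mi[i]))]
      if (!anyNA(dp)) depth[i] <- max(dp, 0L) + 1L
    }
  }
  if (anyNA(depth)) {
    abort(paste("pedigree contains a cycle involving:",
                paste(ids[is.na(depth)], collapse = ", ")))
  }
  ord <- order(depth)
  phi <- matrix(0, n, n)
  for (i in ord) {
    pf <- fi[i]; pm <- mi[i]
    phi_fm <- if (!is.na(pf) && !is.na(pm)) phi[pf, pm] else 0
    phi[i, i] <- 0.5 * (1 + phi_fm)
    earlier <- ord[seq_len(which(ord == i) - 1)]
    for (j in earlier) {
      v <- 0
      if (!is.na(pf)) v <- v + 0.5 * phi[pf, j]
      if (!is.na(pm)) v <- v + 0.5 * phi[pm, j]
      phi[i, j] <- phi[j, i] <- v
    }
  }
  A <- 2 * phi
  dimnames(A) <- list(ids, ids)
  structure(list(matrix = A, subject_ids = ids), class = "microfam_kinship")
}

#' @export
print.microfam_kinship <- function(x, ...) {
  cat("<microfam_kinship> ", length(x$subject_ids), " subjects\n", sep = "")
  invisible(x)
}

# Rotated REML/ML for y = Xb + g + e, g ~ N(0, sg2 A), e ~ N(0, se2 I).
h2_core <- function(y, X, eig) {
  n <- length(y)
  p <- ncol(X)
  U <- eig$vectors; lam <- eig$values
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)

  prof <- function(lgamma_, reml = TRUE) {
    g <- exp(lgamma_)
    w <- 1 / (g * lam + 1)
    XtWX <- crossprod(Xr * w, Xr)
    b <- tryCatch(solve(XtWX, crossprod(Xr * w, yr)), error = function(e) NULL)
    if (is.null(b)) return(list(ll = -Inf))
    r <- yr - Xr %*% b
    rss <- sum(w * r^2)
    if (reml) {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(g * lam + 1)) +
                      as.numeric(determinant(XtWX)$modulus) + (n - p))
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(g * lam + 1)) + n)
    }
    list(ll = ll, s2 = s2, beta = b, gamma = g)
  }

  lo <- -14; hi <- 14
  opt <- optimize(function(lg) prof(lg)$ll, c(lo, hi), maximum = TRUE, tol = 1e-10)
  at <- prof(opt$maximum)
  ll0 <- prof(lo)$ll
  flat <- abs(at$ll - ll0) < 1e-6 && abs(opt$maximum - lo) > 1
  unident <- sd(lam) < 1e-10 || flat
  boundary <- opt$maximum < lo + 0.5 || opt$maximum > hi - 0.5
  gamma <- if (boundary && opt$maximum < lo + 0.5) 0 else at$gamma
  h2 <- gamma / (1 + gamma)
  se2 <- at$s2
  sg2 <- gamma * se2

  opt_ml <- optimize(function(lg) prof(lg, reml = FALSE)$ll, c(lo, hi),
                     maximum = TRUE, tol = 1e-10)
  ll_ml <- prof(opt_ml$maximum, reml = FALSE)$ll
  aic <- 2 * (p + 2) - 2 * ll_ml

  list(h2 = min(max(h2, 0), 1), sigma_g2 = sg2, sigma_e2 = se2,
       loglik_reml = at$ll, loglik_ml = ll_ml, aic = aic,
       unidentifiable = unident, boundary = boundary, n = n, p = p)
}

#' Heritability of a phenotype from pedigree kinship
#'
#' Fits the linear mixed model `y = X beta + g + e` with
#' `g ~ N(0, sigma_g^2 A)` and `e ~ N(0, sigma_e^2 I)` by restricted
#' maximum likelihood, using the eigendecomposition of `A` to reduce the
#' problem to a one-dimensional search over the variance ratio; the ML fit
#' is re-run for the AIC. `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`,
#' clipped to `[0, 1]` with a boundary flag. With `A` proportional to the
#' identity the two variance components are not identifiable; the fit is
#' flagged rather than returning an arbitrary split.
#'
#' @param phenotype Named numeric vector (names = subject ids), or plain
#'   vector aligned with `subjects`.
#' @param A A `microfam_kinship` or additive relationship matrix.
#' @param covariates Optional data frame / matrix of fixed covariates
#'   (rows follow the phenotype's subjects).
#' @param subjects Subject ids when `phenotype` is unnamed.
#' @return A `microfam_h2` list: `h2`, `sigma_g2`, `sigma_e2`,
#'   `loglik_reml`, `loglik_ml`, `aic`, `n`, `model`, flags
#'   `unidentifiable` / `boundary`.
#' @export
fit_h2 <- function(phenotype, A, covariates = NULL, subjects = NULL) {
  Am <- if (inherits(A, "microfam_kinship")) A$matrix else as.matrix(A)
  ids <- subjects %||% names(phenotype)
  if (is.null(ids)) abort("phenotype must be named or `subjects` given.")
  keep <- is.finite(phenotype)
  X <- if (is.null(covariates)) {
    matrix(1, length(phenotype), 1)
  } else {
    model.matrix(~ ., as.data.frame(covariates))
  }
  keep <- keep & stats::complete.cases(X)
  y <- phenotype[keep]; ids <- ids[keep]; X <- X[keep, , drop = FALSE]
  if (!all(ids %in% rownames(Am))) abort("phenotype subjects missing from the kinship matrix.")
  if (length(y) <= ncol(X) + 2) abort("need n > n_covariates + 2.")
  Am <- Am[ids, ids]
  eig <- eigen(Am, symmetric = TRUE)
  if (min(eig$values) < -1e-6) {
    abort("kinship matrix is not positive semidefinite; consider bending it.")
  }
  eig$values <- pmax(eig$values, 0)
  res <- h2_core(y, X, eig)
  res$model <- if (is.null(covariates)) "null" else "full"
  structure(res, class = "microfam_h2")
}

#' @export
print.microfam_h2 <- function(x, ...) {
  cat("<microfam_h2> model:", x$model,
      " h2 =", signif(x$h2, 4),
      " (sg2 =", signif(x$sigma_g2, 4),
      ", se2 =", signif(x$sigma_e2, 4), ") AIC =", signif(x$aic, 6), "\n")
  if (x$unidentifiable) cat("note: variance components not identifiable (flat likelihood)\n")
  invisible(x)
}

#' Heritability with and without covariates
#'
#' Fits the kinship mixed model twice on the identical subject set -- once
#' without fixed covariates (`h2_null`) and once with them (`h2_full`) --
#' and reports both estimates plus `delta_aic = AIC_null - AIC_full`
#' (positive = covariates improve the ML fit). Subjects with any missing
#' covariate are dropped from both models so the AICs are comparable.
#'
#' @inheritParams fit_h2
#' @param covariates Data frame of fixed covariates (e.g. age, sex, BMI,
#'   IBD status).
#' @return List with `null`, `full` (both `microfam_h2`), `delta_aic`, `n`.
#' @export
compare_h2_models <- function(phenotype, A, covariates, subjects = NULL) {
  ids <- subjects %||% names(phenotype)
  cv <- as.data.frame(covariates)
  keep <- is.finite(phenotype) & stats::complete.cases(cv)
  y <- setNames(phenotype[keep], ids[keep])
  cv <- cv[keep, , drop = FALSE]
  null <- fit_h2(y, A)
  full <- fit_h2(y, A, covariates = cv)
  list(null = null, full = full, delta_aic = null$aic - full$aic, n = null$n)
}

#' Per-taxon heritability scan of CLR abundances
#'
#' Restricts to the baseline time point (when a `time_point` column is
#' present), applies a prevalence cutoff (default: taxon present in at
#' least 10% of samples), CLR-transforms the counts, and fits the null and
#' full (age, sex, BMI, IBD status) kinship models per taxon.
#'
#' @param counts Wide count table or matrix.
#' @param metadata Metadata with `sample_id`, `subject_id`, `age`, `sex`,
#'   `bmi`, `diagnosis` (and optionally `time_point`).
#' @param pedigree Pedigree data frame (see [kinship_matrix()]).
#' @param prevalence_cutoff Minimum fraction of samples with a nonzero
#'   count.
#' @param pseudocount CLR pseudocount.
#' @return Tibble `taxon_id`, `h2_null`, `h2_full`, `aic_null`, `aic_full`,
#'   `delta_aic`, `n`.
#' @export
heritability_scan <- function(counts, metadata, pedigree,
                              prevalence_cutoff = 0.10, pseudocount = 0.5) {
  m <- count_matrix(counts)
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if ("time_point" %in% names(md)) {
    bl <- md$time_point == "BL" | is.na(md$time_point)
    m <- m[bl, , drop = FALSE]; md <- md[bl, , drop = FALSE]
  }
  keep <- colMeans(m > 0) >= prevalence_cutoff
  m <- m[, keep, drop = FALSE]
  clr <- value_matrix(clr_transform(m, pseudocount))
  K <- kinship_matrix(pedigree)
  cv <- data.frame(age = md$age, sex = md$sex, bmi = md$bmi,
                   ibd = md$diagnosis != "Control")
  ok <- stats::complete.cases(cv)
  clr <- clr[ok, , drop = FALSE]; md <- md[ok, , drop = FALSE]
  cv <- cv[ok, , drop = FALSE]
  ids <- md$subject_id
  Am <- K$matrix[ids, ids]
  eig <- eigen(Am, symmetric = TRUE)
  eig$values <- pmax(eig$values, 0)
  X0 <- matrix(1, nrow(clr), 1)
  X1 <- model.matrix(~ age + sex + bmi + ibd, cv)
  rows <- purrr::map(colnames(clr), function(tx) {
    y <- clr[, tx]
    f0 <- h2_core(y, X0, eig)
    f1 <- h2_core(y, X1, eig)
    tibble::tibble(taxon_id = tx, h2_null = f0$h2, h2_full = f1$h2,
                   aic_null = f0$aic, aic_full = f1$aic,
                   delta_aic = f0$aic - f1$aic, n = f0$n)
  })
  dplyr::bind_rows(rows)
}
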