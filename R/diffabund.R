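# Per-taxon negative-binomial Wald tests with covariates, filtering and FDR.

nb_family <- function(theta) MASS::negative.binomial(theta = theta, link = "log")

nb_fit_once <- function(y, X, off, theta) {
  fit <- suppressWarnings(glm.fit(X, y, offset = off, family = nb_family(theta),
                                  control = list(maxit = 50)))
  fit
}

nb_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu) + (y == 0)))
}

cox_reid_apl <- function(y, X, off, theta) {
  fit <- nb_fit_once(y, X, off, theta)
  if (!fit$converged) return(-Inf)
  mu <- fit$fitted.values
  w <- mu / (1 + mu / theta)
  xtwx <- crossprod(X * sqrt(w))
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  nb_loglik(y, mu, theta) - 0.5 * as.numeric(ld)
}

#' Fit a negative-binomial GLM for one taxon
#'
#' Log-link NB regression of one taxon's counts on a covariate design with
#' `log(size_factor)` offsets. When `dispersion` is `NULL`, the per-taxon
#' dispersion (`alpha = 1/theta`; variance `mu + alpha mu^2`) is estimated
#' by maximising the Cox-Reid adjusted profile likelihood. Wald statistics
#' are `beta / SE` from the observed-information covariance.
#'
#' @param y Integer count vector.
#' @param design Numeric design matrix (with intercept column).
#' @param size_factors Positive per-sample size factors (vector).
#' @param dispersion Optional fixed dispersion `alpha`; estimated if `NULL`.
#' @return List with `coefficients`, `se`, `vcov`, `dispersion` (alpha),
#'   `base_mean` (mean normalised count), `loglik`, `converged`.
#' @export
fit_nb_glm <- function(y, design, size_factors, dispersion = NULL) {
  X <- as.matrix(design)
  if (qr(X)$rank < ncol(X)) abort("rank-deficient design matrix.")
  if (length(y) != nrow(X)) abort("`y` and `design` dimensions differ.")
  if (any(size_factors <= 0)) abort("size factors must be strictly positive.")
  off <- log(size_factors)
  if (is.null(dispersion)) {
    opt <- optimize(function(lt) cox_reid_apl(y, X, off, exp(lt)),
                    interval = c(-8, 16), maximum = TRUE, tol = 1e-4)
    theta <- exp(opt$maximum)
  } else {
    theta <- 1 / max(dispersion, 1e-12)
  }
  fit <- nb_fit_once(y, X, off, theta)
  mu <- fit$fitted.values
  w <- mu / (1 + mu / theta)
  xtwx <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(xtwx), error = function(e) NULL)
  conv <- fit$converged && !is.null(V) && all(is.finite(V))
  list(coefficients = coef(fit), se = if (conv) sqrt(diag(V)) else rep(NA, ncol(X)),
       vcov = V, dispersion = 1 / theta, base_mean = mean(y / size_factors),
       loglik = nb_loglik(y, mu, theta), converged = conv)
}

# Dispersion trend a/mu + b and log-normal shrinkage toward it.
shrink_dispersions <- function(alpha, base_mean, n, p) {
  ok <- is.finite(alpha) & alpha > 1e-8 & base_mean > 0
  a <- b <- NA
  if (sum(ok) >= 10) {
    fit <- lm(alpha[ok] ~ I(1 / base_mean[ok]))
    a <- max(coef(fit)[2], 0)
    b <- max(coef(fit)[1], 1e-8)
  } else {
    b <- max(median(alpha[ok]), 1e-8)
    a <- 0
  }
  trend <- pmax(a / base_mean + b, 1e-8)
  s2_samp <- trigamma(pmax((n - p) / 2, 1))
  delta <- log(pmax(alpha, 1e-8)) - log(trend)
  tau2 <- max(var(delta[ok]) - s2_samp, 0.05)
  w <- tau2 / (tau2 + s2_samp)
  exp(w * log(pmax(alpha, 1e-8)) + (1 - w) * log(trend))
}

diag_contrasts <- list(
  CD_vs_Control = c("diagnosisCD", NA),
  UC_vs_Control = c("diagnosisUC", NA),
  CD_vs_UC = c("diagnosisCD", "diagnosisUC")
)

#' Differential abundance across diagnosis groups
#'
#' Applies the prevalence filter, fits a negative-binomial GLM per taxon
#' with covariates (`sex + scaled BMI + scaled age`, plus time point when
#' several are present) and size-factor offsets, estimates dispersions with
#' shrinkage toward a mean-dispersion trend, and reports Wald tests for the
#' requested contrasts with Benjamini-Hochberg FDR within each contrast.
#' The `IBD_vs_Control` contrast uses a separate fit with diagnosis
#' collapsed to Control/IBD; uIBD samples take part in model fitting but in
#' no pairwise pathology contrast.
#'
#' @param counts Wide count table or matrix (integer counts).
#' @param metadata Metadata with `sample_id`, `diagnosis` and the covariate
#'   columns.
#' @param contrasts Subset of `CD_vs_Control`, `UC_vs_Control`, `CD_vs_UC`,
#'   `IBD_vs_Control`.
#' @param covariates One-sided formula of adjustment covariates.
#' @param filter Apply [prevalence_filter()] with its defaults first.
#' @param shrink Shrink dispersions toward the fitted trend.
#' @return Tibble with `taxon_id`, `base_mean`, `log2_fold_change`,
#'   `lfc_se`, `wald_stat`, `p_value`, `p_fdr`, `contrast`. Non-converged
#'   taxa are dropped from the FDR family and flagged by attribute
#'   `n_not_converged`.
#' @export
run_diffabund <- function(counts, metadata,
                          contrasts = c("CD_vs_Control", "UC_vs_Control",
                                        "CD_vs_UC", "IBD_vs_Control"),
                          covariates = ~ sex + scale(bmi) + scale(age),
                          filter = TRUE, shrink = TRUE) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  m <- count_matrix(counts, require_integer = TRUE)
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) abort("metadata is missing some samples.")
  if (!"diagnosis" %in% names(md)) abort("metadata must contain `diagnosis`.")
  md$diagnosis <- droplevels(factor(md$diagnosis,
                                    levels = c("Control", "CD", "UC", "uIBD")))
  need_lv <- unique(unlist(strsplit(setdiff(contrasts, "IBD_vs_Control"), "_vs_")))
  if (!all(need_lv %in% levels(md$diagnosis))) {
    abort("a contrast level is absent from the data.")
  }

  sf <- size_factors(m, pseudo_reference = TRUE)
  if (filter) {
    m <- count_matrix(prevalence_filter(m, size_factors = sf))
  }
  sfv <- sf$size_factor[match(rownames(m), sf$sample_id)]

  rhs <- paste(attr(terms(covariates), "term.labels"), collapse = " + ")
  if ("time_point" %in% names(md) && length(unique(md$time_point)) > 1) {
    rhs <- paste(rhs, "+ time_point")
  }
  out <- list()

  fit_model <- function(group_col, wanted) {
    f <- as.formula(paste("~", rhs, "+", group_col))
    X <- model.matrix(f, md)
    n <- nrow(X); p <- ncol(X)
    fits <- apply(m, 2, function(y) {
      tryCatch(fit_nb_glm(y, X, sfv), error = function(e) NULL)
    })
    alpha <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$dispersion, 0)
    bm <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$base_mean, 0)
    if (shrink) {
      alpha_s <- shrink_dispersions(alpha, bm, n, p)
      fits <- purrr::map2(asplit(m, 2), alpha_s, function(y, a) {
        tryCatch(fit_nb_glm(as.numeric(y), X, sfv, dispersion = a),
                 error = function(e) NULL)
      })
    }
    res <- purrr::imap(wanted, function(cv, lab) {
      rows <- purrr::imap(fits, function(f, taxon) {
        if (is.null(f) || !f$converged) return(NULL)
        i1 <- match(cv[1], names(f$coefficients))
        est <- f$coefficients[i1]
        v <- f$vcov[i1, i1]
        if (!is.na(cv[2])) {
          i2 <- match(cv[2], names(f$coefficients))
          est <- est - f$coefficients[i2]
          v <- v + f$vcov[i2, i2] - 2 * f$vcov[i1, i2]
        }
        tibble::tibble(taxon_id = taxon, base_mean = f$base_mean,
                       log2_fold_change = est / log(2),
                       lfc_se = sqrt(v) / log(2),
                       wald_stat = est / sqrt(v),
                       p_value = 2 * pnorm(-abs(est / sqrt(v))))
      })
      tab <- dplyr::bind_rows(rows)
      tab$p_fdr <- p.adjust(tab$p_value, method = "BH")
      tab$contrast <- lab
      tab
    })
    list(res = dplyr::bind_rows(res),
         n_bad = sum(vapply(fits, function(f) is.null(f) || !f$converged, TRUE)))
  }

  n_bad <- 0
  diag_wanted <- diag_contrasts[intersect(contrasts, names(diag_contrasts))]
  if (length(diag_wanted) > 0) {
    fm <- fit_model("diagnosis", diag_wanted)
    out <- c(out, list(fm$res)); n_bad <- n_bad + fm$n_bad
  }
  if ("IBD_vs_Control" %in% contrasts) {
    md$health_status <- factor(ifelse(md$diagnosis == "Control", "Control", "IBD"),
                               levels = c("Control", "IBD"))
    fm <- fit_model("health_status",
                    list(IBD_vs_Control = c("health_statusIBD", NA)))
    out <- c(out, list(fm$res)); n_bad <- n_bad + fm$n_bad
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_not_converged") <- n_bad
  res
}
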