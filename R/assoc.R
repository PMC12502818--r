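# Covariate-adjusted models, partial correlations, Brown's method, and
# rank tests for group/cluster characterisation.

#' Partial correlation via the precision-matrix formula
#'
#' Computes the partial correlation of `x` and `y` given covariates from
#' the inverse of the joint correlation matrix:
#' `rho_xy.z = -P_xy / sqrt(P_xx P_yy)`. Spearman and Kendall variants use
#' the rank-based correlation matrix in the same formula (the Kendall
#' variant is the usual approximation). P-values use the t approximation at
#' `n - k - 2` degrees of freedom (Pearson/Spearman) or the normal
#' approximation (Kendall).
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame of covariates; with
#'   none, the result equals the plain correlation.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return Tibble with `method`, `estimate`, `statistic`, `p_value`, `n`,
#'   `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  k <- if (is.null(Z)) 0 else ncol(Z)
  dat <- cbind(x = x, y = y, Z)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= k + 2) abort("need n > n_covariates + 2 observations.")
  R <- cor(dat, method = method)
  if (abs(R[1, 2]) >= 1 - 1e-12) {
    # x and y are (anti)identical up to the transform: partial rho = +/-1
    rho <- sign(R[1, 2])
  } else {
    P <- tryCatch(solve(R), error = function(e) {
      abort("singular correlation matrix; covariates may be collinear.")
    })
    rho <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    rho <- max(min(rho, 1), -1)
  }
  if (method %in% c("pearson", "spearman")) {
    df <- n - k - 2
    stat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(stat), df)
  } else {
    stat <- rho / sqrt(2 * (2 * (n - k) + 5) / (9 * (n - k) * (n - 1 - k)))
    p <- 2 * pnorm(-abs(stat))
  }
  tibble::tibble(method = method, estimate = rho, statistic = stat,
                 p_value = p, n = n, n_covariates = k)
}

#' Combine dependent p-values by Brown's method
#'
#' Extends Fisher's method to correlated tests: with
#' `X = -2 sum(log p_i)`, the mean is `2k` and the variance
#' `4k + 2 sum_{i<j} cov_ij`, where each covariance is approximated from
#' the correlation `rho_ij` of the underlying statistics by the
#' Kost-McDermott polynomial `3.263 rho + 0.710 rho^2 + 0.027 rho^3`. `X`
#' is referred to a scaled chi-square with matched moments. With a zero (or
#' absent) correlation matrix this is exactly Fisher's method.
#'
#' @param p_values Vector of p-values in (0, 1]; exact zeros are clamped to
#'   the smallest representable double with a warning.
#' @param inter_test_correlations Optional symmetric correlation matrix of
#'   the tests (identity if `NULL`).
#' @return Combined p-value (scalar).
#' @export
browns_combine <- function(p_values, inter_test_correlations = NULL) {
  p <- p_values
  if (any(p <= 0)) {
    warn("p-values of 0 clamped to the machine minimum.")
    p[p <= 0] <- .Machine$double.xmin
  }
  if (any(p > 1)) abort("p-values must be in (0, 1].")
  k <- length(p)
  X <- -2 * sum(log(p))
  e_x <- 2 * k
  var_x <- 4 * k
  R <- inter_test_correlations
  if (!is.null(R)) {
    R <- as.matrix(R)
    if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
      abort("the inter-test correlation matrix must be positive semidefinite.")
    }
    rho <- R[upper.tri(R)]
    var_x <- var_x + 2 * sum(3.263 * rho + 0.710 * rho^2 + 0.027 * rho^3)
  }
  f <- 2 * e_x^2 / var_x
  c_scale <- var_x / (2 * e_x)
  pchisq(X / c_scale, df = f, lower.tail = FALSE)
}

#' Taxa-phenotype combined-correlation scan
#'
#' For each (taxon, phenotype) pair, computes covariate-adjusted partial
#' correlations by all three methods (Pearson, Spearman, Kendall) on CLR
#' abundances, combines the three p-values with Brown's method, and applies
#' Benjamini-Hochberg FDR across the scan. The inter-method correlation
#' matrix is, by default, estimated empirically per phenotype from the
#' `-2 log p` vectors across taxa; a fixed matrix may be supplied instead.
#'
#' @param counts Wide count table or matrix (CLR-transformed internally
#'   unless `clr = FALSE`, in which case values are used as given).
#' @param metadata Metadata with `sample_id`, the phenotype columns, and
#'   the adjustment covariates.
#' @param phenotypes Character vector of metadata columns to scan.
#' @param adjust_for Covariate columns (factors are coded numerically).
#' @param clr Apply [clr_transform()] first.
#' @param pseudocount CLR pseudocount.
#' @param correlation_matrix Optional fixed 3x3 inter-method correlation
#'   matrix for Brown's method.
#' @return Tibble `taxon_id`, `phenotype`, `rho_spearman`, `p_pearson`,
#'   `p_spearman`, `p_kendall`, `brown_p`, `brown_p_fdr`.
#' @export
correlation_scan <- function(counts, metadata, phenotypes,
                             adjust_for = c("age", "sex", "bmi"),
                             clr = TRUE, pseudocount = 0.5,
                             correlation_matrix = NULL) {
  m <- value_matrix(if (clr) clr_transform(counts, pseudocount) else counts)
  md <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  Z <- as.matrix(as.data.frame(lapply(md[adjust_for], function(col) {
    if (is.numeric(col)) col else as.numeric(as.factor(col))
  })))
  methods <- c("pearson", "spearman", "kendall")
  out <- purrr::map(phenotypes, function(ph) {
    yv <- md[[ph]]
    rows <- purrr::map(colnames(m), function(tx) {
      res <- purrr::map(methods, function(me) {
        partial_correlation(m[, tx], yv, Z, method = me)
      })
      res <- dplyr::bind_rows(res)
      tibble::tibble(taxon_id = tx, phenotype = ph,
                     rho_spearman = res$estimate[res$method == "spearman"],
                     p_pearson = res$p_value[res$method == "pearson"],
                     p_spearman = res$p_value[res$method == "spearman"],
                     p_kendall = res$p_value[res$method == "kendall"])
    })
    tab <- dplyr::bind_rows(rows)
    R <- correlation_matrix
    if (is.null(R) && nrow(tab) >= 5) {
      lp <- -2 * log(pmax(as.matrix(tab[c("p_pearson", "p_spearman", "p_kendall")]),
                          .Machine$double.xmin))
      R <- suppressWarnings(cor(lp))
      if (anyNA(R)) R <- NULL
    }
    tab$brown_p <- vapply(seq_len(nrow(tab)), function(i) {
      browns_combine(c(tab$p_pearson[i], tab$p_spearman[i], tab$p_kendall[i]), R)
    }, 0)
    tab
  })
  res <- dplyr::bind_rows(out)
  res$brown_p_fdr <- p.adjust(res$brown_p, method = "BH")
  res
}

#' Rank and paired tests for group characterisation
#'
#' Kruskal-Wallis for more than two groups (with pairwise Wilcoxon
#' follow-ups, FDR-adjusted), Wilcoxon rank-sum for two groups, or a paired
#' t-test when a pairing column is given.
#'
#' @param data Data frame.
#' @param value,group Column names of the response and grouping factor.
#' @param paired_by Optional column naming the pairing unit (two groups
#'   only); rows are matched on it and a paired t-test is run.
#' @return Tibble `comparison`, `method`, `statistic`, `p_value`, `p_fdr`.
#' @export
group_tests <- function(data, value, group, paired_by = NULL) {
  v <- data[[value]]
  g <- droplevels(as.factor(data[[group]]))
  if (any(table(g) == 0) || nlevels(g) < 2) abort("need >= 2 nonempty groups.")
  if (!is.null(paired_by)) {
    if (nlevels(g) != 2) abort("paired tests need exactly two groups.")
    wide <- tidyr::pivot_wider(
      tibble::tibble(id = data[[paired_by]], g = g, v = v),
      names_from = "g", values_from = "v")
    if (anyNA(wide)) abort("pairing is incomplete.")
    tt <- t.test(wide[[2]], wide[[3]], paired = TRUE)
    return(tibble::tibble(
      comparison = paste(levels(g), collapse = " vs "),
      method = "paired t-test", statistic = unname(tt$statistic),
      p_value = tt$p.value, p_fdr = tt$p.value))
  }
  if (nlevels(g) == 2) {
    wt <- wilcox.test(v ~ g)
    return(tibble::tibble(
      comparison = paste(levels(g), collapse = " vs "),
      method = "wilcoxon rank-sum", statistic = unname(wt$statistic),
      p_value = wt$p.value, p_fdr = wt$p.value))
  }
  kw <- kruskal.test(v, g)
  pairs <- combn(levels(g), 2, simplify = FALSE)
  pw <- purrr::map(pairs, function(pr) {
    sel <- g %in% pr
    wt <- wilcox.test(v[sel] ~ droplevels(g[sel]))
    tibble::tibble(comparison = paste(pr, collapse = " vs "),
                   method = "wilcoxon rank-sum",
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_fdr <- p.adjust(pw$p_value, method = "BH")
  dplyr::bind_rows(
    tibble::tibble(comparison = "omnibus", method = "kruskal-wallis",
                   statistic = unname(kw$statistic), p_value = kw$p.value,
                   p_fdr = kw$p.value),
    pw)
}

#' Covariate-adjusted group/phenotype linear model
#'
#' Two-stage analysis: the response is first residualised on
#' `sex + scaled BMI + scaled age`, then the residuals are modelled on
#' `diagnosis * phenotype` (or `diagnosis` alone). Backward/forward
#' stepwise selection minimises AIC, and pairwise group contrasts of means
#' (and of slopes, when the interaction survives selection) are computed
#' with FDR adjustment across the contrast family. A joint (single-stage)
#' fit is available with `two_stage = FALSE`.
#'
#' @param data Data frame with the response, group, phenotype and covariate
#'   columns; rows with missing values are dropped (count reported).
#' @param response Response column name.
#' @param group Grouping column (default `diagnosis`).
#' @param phenotype Optional phenotype column interacting with the group.
#' @param covariates One-sided formula of stage-1 covariates.
#' @param stepwise Run stepwise AIC selection on the stage-2 model.
#' @return A `microfam_adjlm`: final `model`, `contrasts` tibble,
#'   `aic_trace`, `n_dropped`. Groups with fewer than 3 observations are
#'   excluded from contrasts with a warning.
#' @export
fit_adjusted_lm <- function(data, response, group = "diagnosis",
                            phenotype = NULL,
                            covariates = ~ sex + scale(bmi) + scale(age),
                            stepwise = TRUE, two_stage = TRUE) {
  if (!requireNamespace("emmeans", quietly = TRUE)) {
    abort("the emmeans package is required for group contrasts.")
  }
  used <- c(response, group, phenotype, all.vars(covariates))
  d <- data[used]
  n0 <- nrow(d)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_dropped <- n0 - nrow(d)
  if (n_dropped > 0) inform(sprintf("dropped %d incomplete row(s).", n_dropped))
  d[[group]] <- droplevels(as.factor(d[[group]]))

  if (two_stage) {
    stage1 <- lm(reformulate(attr(terms(covariates), "term.labels"), response), d)
    d$.resid <- resid(stage1)
    rhs <- if (is.null(phenotype)) group else paste(group, "*", phenotype)
    fit <- lm(as.formula(paste(".resid ~", rhs)), d)
  } else {
    rhs <- paste(c(attr(terms(covariates), "term.labels"),
                   if (is.null(phenotype)) group else paste(group, "*", phenotype)),
                 collapse = " + ")
    fit <- lm(as.formula(paste(response, "~", rhs)), d)
  }
  aic_trace <- tibble::tibble(step = "initial", aic = AIC(fit))
  if (stepwise) {
    fit <- step(fit, direction = "both", trace = 0)
    aic_trace <- dplyr::bind_rows(
      aic_trace, tibble::tibble(step = "final", aic = AIC(fit)))
  }

  small <- names(which(table(d[[group]]) < 3))
  if (length(small) > 0) {
    warn(paste("suppressing contrasts for small group(s):",
               paste(small, collapse = ", ")))
  }
  keep_lv <- setdiff(levels(d[[group]]), small)
  ctr <- tibble::tibble()
  in_model <- all.vars(formula(fit))
  both_kept <- function(cmp) {
    Reduce(`+`, lapply(keep_lv, function(l) grepl(l, cmp, fixed = TRUE))) == 2
  }
  if (group %in% in_model) {
    em <- suppressMessages(emmeans::emmeans(fit, specs = group))
    mc <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
    mc <- mc[both_kept(mc$contrast), ]
    ctr <- tibble::tibble(comparison = mc$contrast, type = "mean",
                          estimate = mc$estimate, se = mc$SE,
                          p_value = mc$p.value)
    if (!is.null(phenotype) && any(grepl(":", attr(terms(fit), "term.labels")))) {
      tr <- suppressMessages(emmeans::emtrends(fit, specs = group, var = phenotype))
      sc <- as.data.frame(emmeans::contrast(tr, method = "pairwise", adjust = "none"))
      sc <- sc[both_kept(sc$contrast), ]
      ctr <- dplyr::bind_rows(ctr, tibble::tibble(
        comparison = sc$contrast, type = "slope",
        estimate = sc$estimate, se = sc$SE, p_value = sc$p.value))
    }
    ctr$p_fdr <- p.adjust(ctr$p_value, method = "BH")
  }
  structure(list(model = fit, contrasts = ctr, aic_trace = aic_trace,
                 n_dropped = n_dropped, group = group, phenotype = phenotype),
            class = "microfam_adjlm")
}

#' @export
print.microfam_adjlm <- function(x, ...) {
  cat("<microfam_adjlm> final AIC:", signif(AIC(x$model), 6), "\n")
  cat("terms:", deparse(formula(x$model)), "\n")
  if (nrow(x$contrasts) > 0) print(as.data.frame(x$contrasts))
  invisible(x)
}
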