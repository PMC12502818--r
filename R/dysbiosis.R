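# Modified microbial dysbiosis (MD) index: taxon-set derivation, scoring,
# and the dysbiosis-diversity curve with AIC model selection.

#' Derive disease-up / health-up taxon sets
#'
#' Combines baseline differential-abundance results for the CD-vs-Control
#' and UC-vs-Control contrasts: taxa significantly *up* in either CD or UC
#' form the IBD-associated set, taxa significantly *down* in either form
#' the control-associated set. Taxa significant in opposite directions in
#' the two contrasts are dropped with a warning so the sets stay disjoint.
#'
#' @param results Differential-abundance tibble from [run_diffabund()]
#'   containing the `CD_vs_Control` and `UC_vs_Control` contrasts (or any
#'   subset of contrasts named in `use_contrasts`).
#' @param alpha_fdr FDR significance threshold (default 0.05).
#' @param use_contrasts Contrasts to combine.
#' @return A `microfam_mdsets` list: `ibd_up`, `control_up` (character
#'   vectors of taxon ids) and `source` (provenance record).
#' @export
derive_md_taxa <- function(results, alpha_fdr = 0.05,
                           use_contrasts = c("CD_vs_Control", "UC_vs_Control")) {
  res <- dplyr::filter(results, .data$contrast %in% use_contrasts)
  if (nrow(res) == 0) abort("no rows for the requested contrasts.")
  sig <- dplyr::filter(res, .data$p_fdr <= alpha_fdr)
  ibd_up <- unique(sig$taxon_id[sig$log2_fold_change > 0])
  control_up <- unique(sig$taxon_id[sig$log2_fold_change < 0])
  conflict <- intersect(ibd_up, control_up)
  if (length(conflict) > 0) {
    warn(paste("dropping taxa significant in opposite directions:",
               paste(conflict, collapse = ", ")))
    ibd_up <- setdiff(ibd_up, conflict)
    control_up <- setdiff(control_up, conflict)
  }
  structure(list(ibd_up = ibd_up, control_up = control_up,
                 source = list(contrasts = use_contrasts, alpha_fdr = alpha_fdr,
                               universe = unique(res$taxon_id))),
            class = "microfam_mdsets")
}

#' @export
print.microfam_mdsets <- function(x, ...) {
  cat("<microfam_mdsets> ", length(x$ibd_up), " IBD-associated, ",
      length(x$control_up), " control-associated taxa (FDR ",
      x$source$alpha_fdr, ")\n", sep = "")
  invisible(x)
}

#' Modified microbial dysbiosis index
#'
#' Per sample, `MD = log1p(sum of abundances over IBD-associated taxa) /
#' log1p(sum over control-associated taxa)` on size-factor-normalised
#' counts (or relative abundances). Values are non-negative; samples whose
#' denominator sum is zero are undefined and returned as `NA`.
#'
#' @param counts Wide count table or matrix (raw counts; normalised
#'   internally according to `basis`).
#' @param sets A `microfam_mdsets` from [derive_md_taxa()].
#' @param basis `"normalized"` (median-of-ratios, default) or
#'   `"relative"` abundances as the abundance scale. The ratio of `log1p`
#'   terms is invariant to the base of the logarithm, so none is exposed.
#' @return Tibble `sample_id`, `md`, `numerator`, `denominator`; attribute
#'   `n_undefined` counts the denominator-zero samples.
#' @export
md_index <- function(counts, sets, basis = c("normalized", "relative")) {
  basis <- match.arg(basis)
  stopifnot(inherits(sets, "microfam_mdsets"))
  if (length(sets$ibd_up) == 0 || length(sets$control_up) == 0) {
    abort("both taxon sets must be nonempty.")
  }
  m <- count_matrix(counts)
  missing_taxa <- setdiff(c(sets$ibd_up, sets$control_up), colnames(m))
  if (length(missing_taxa) > 0) {
    abort(paste("taxa absent from the count table:",
                paste(missing_taxa, collapse = ", ")))
  }
  norm <- if (basis == "normalized") {
    sf <- size_factors(m, pseudo_reference = TRUE)
    sweep(m, 1, sf$size_factor[match(rownames(m), sf$sample_id)], `/`)
  } else {
    sweep(m, 1, rowSums(m), `/`)
  }
  num_sum <- rowSums(norm[, sets$ibd_up, drop = FALSE])
  den_sum <- rowSums(norm[, sets$control_up, drop = FALSE])
  md <- log1p(num_sum) / log1p(den_sum)
  md[den_sum == 0] <- NA_real_
  if (anyNA(md)) warn(sprintf("%d sample(s) have zero denominator: MD set to NA.",
                              sum(is.na(md))))
  out <- tibble::tibble(sample_id = rownames(m), md = unname(md),
                        numerator = unname(num_sum), denominator = unname(den_sum))
  attr(out, "basis") <- basis
  attr(out, "n_undefined") <- sum(is.na(md))
  out
}

segmented_rss <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Dysbiosis-diversity curve with AIC model selection
#'
#' Fits three nested candidates for the relationship between a diversity
#' measure and the MD-index -- linear, quadratic, and segmented linear with
#' one breakpoint (continuous at the break, profiled over a grid of 200
#' candidate breakpoints between the 5th and 95th percentile of the MD
#' values) -- and selects the minimum-AIC model. The segmented model's AIC
#' charges two effective parameters for the breakpoint: one for the
#' parameter itself and one for the selection bias of profiling it over the
#' whole grid (a Davies-type correction; without it, spurious breakpoints
#' are picked on linear truth far more often than the nominal AIC exchange
#' rate suggests). The profile confidence interval collects grid points
#' within the chi-square cutoff of the minimum residual sum of squares.
#'
#' @param data Data frame holding the two variables.
#' @param md,diversity Column names (strings) of the MD-index (predictor)
#'   and diversity (response).
#' @param grid_size Number of breakpoint candidates.
#' @param conf_level Profile CI level for the breakpoint.
#' @return A `microfam_curve` with elements `selected` (model name), `fits`
#'   (per-model AIC table), `breakpoint` (+ CI, segmented only) and the
#'   fitted `lm` objects. `tidy()`, `glance()` and `autoplot()` apply.
#' @export
fit_dysbiosis_diversity_model <- function(data, md = "md", diversity = "value",
                                          grid_size = 200, conf_level = 0.95) {
  x <- data[[md]]; y <- data[[diversity]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 10) abort("need at least 10 paired observations.")
  if (sd(x) == 0) abort("the MD predictor is constant.")

  d <- data.frame(x = x, y = y)
  fit_lin <- lm(y ~ x, data = d)
  fit_quad <- lm(y ~ x + I(x^2), data = d)

  grid <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = grid_size)
  rss <- vapply(grid, function(p) segmented_rss(x, y, p), 0)
  psi <- grid[which.min(rss)]
  d$hinge <- pmax(x - psi, 0)
  fit_seg <- lm(y ~ x + hinge, data = d)
  aic_seg <- AIC(fit_seg) + 4 # breakpoint + profiling correction (2 df)
  cutoff <- min(rss) * exp(qchisq(conf_level, 1) / n)
  ci <- range(grid[rss <= cutoff])

  aics <- c(linear = AIC(fit_lin), quadratic = AIC(fit_quad), segmented = aic_seg)
  selected <- names(which.min(aics))
  structure(list(
    selected = selected,
    fits = tibble::tibble(model = names(aics), aic = unname(aics),
                          r_squared = c(summary(fit_lin)$r.squared,
                                        summary(fit_quad)$r.squared,
                                        summary(fit_seg)$r.squared)),
    breakpoint = if (selected == "segmented") psi else NA_real_,
    breakpoint_estimate = psi,
    breakpoint_ci = ci,
    models = list(linear = fit_lin, quadratic = fit_quad, segmented = fit_seg),
    n = n, md_col = md, diversity_col = diversity
  ), class = "microfam_curve")
}

#' @export
print.microfam_curve <- function(x, ...) {
  cat("<microfam_curve> selected:", x$selected, "(n =", x$n, ")\n")
  print(as.data.frame(x$fits))
  if (x$selected == "segmented") {
    cat("breakpoint:", signif(x$breakpoint, 4), " CI [",
        signif(x$breakpoint_ci[1], 4), ",", signif(x$breakpoint_ci[2], 4), "]\n")
  }
  invisible(x)
}
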