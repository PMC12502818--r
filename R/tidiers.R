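# broom-style tidy()/glance() methods for the package's result objects.

#' @export
tidy.microfam_permanova <- function(x, ...) x$terms

#' @export
glance.microfam_permanova <- function(x, ...) {
  tibble::tibble(adj_R2 = x$adj_R2, n = x$n, n_perm = x$n_perm)
}

#' @export
tidy.microfam_dispersion <- function(x, ...) x$distances

#' @export
glance.microfam_dispersion <- function(x, ...) {
  tibble::tibble(statistic = x$F, p_perm = x$p_perm, n_perm = x$n_perm)
}

#' @export
tidy.microfam_mdsets <- function(x, ...) {
  tibble::tibble(
    taxon_id = c(x$ibd_up, x$control_up),
    set = rep(c("ibd_up", "control_up"), c(length(x$ibd_up), length(x$control_up)))
  )
}

#' @export
tidy.microfam_curve <- function(x, ...) {
  fit <- x$models[[x$selected]]
  s <- summary(fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.microfam_curve <- function(x, ...) {
  tibble::tibble(selected = x$selected,
                 aic = x$fits$aic[x$fits$model == x$selected],
                 r_squared = x$fits$r_squared[x$fits$model == x$selected],
                 breakpoint = x$breakpoint, n = x$n)
}

#' @export
tidy.microfam_dmm <- function(x, ...) x$assignments

#' @export
glance.microfam_dmm <- function(x, ...) {
  tibble::tibble(k = x$k, log_likelihood = x$log_likelihood,
                 laplace_evidence = x$laplace_evidence)
}

#' @export
tidy.microfam_dmm_selection <- function(x, ...) x$trace

#' @export
glance.microfam_dmm_selection <- function(x, ...) {
  tibble::tibble(best_k = x$best_k)
}

#' @export
tidy.microfam_h2 <- function(x, ...) {
  tibble::tibble(model = x$model, h2 = x$h2, sigma_g2 = x$sigma_g2,
                 sigma_e2 = x$sigma_e2, aic = x$aic,
                 unidentifiable = x$unidentifiable, boundary = x$boundary,
                 n = x$n)
}

#' @export
glance.microfam_h2 <- function(x, ...) tidy(x)

#' @export
tidy.microfam_adjlm <- function(x, ...) x$contrasts

#' @export
glance.microfam_adjlm <- function(x, ...) {
  tibble::tibble(aic = AIC(x$model), n_dropped = x$n_dropped,
                 formula = deparse(formula(x$model)))
}

#' @export
tidy.microfam_network <- function(x, ...) x$edges

#' @export
glance.microfam_network <- function(x, ...) global_network_stats(x)
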