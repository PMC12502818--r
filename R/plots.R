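# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_vline
#'   geom_col geom_segment labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an ordination
#'
#' @param object A `microfam_ordination`.
#' @param colour_by Optional vector (e.g. diagnosis) aligned with the
#'   samples, used for point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microfam_ordination <- function(object, colour_by = NULL, ...) {
  d <- object$coordinates
  if (!is.null(colour_by)) d$group <- colour_by
  p <- ggplot(d, aes(x = .data$axis1, y = .data$axis2)) +
    theme_minimal() +
    labs(x = "axis 1", y = "axis 2",
         title = toupper(object$method),
         subtitle = if (!is.null(object$stress))
           paste("stress =", signif(object$stress, 3)) else NULL)
  if (is.null(colour_by)) p + geom_point() else
    p + geom_point(aes(colour = .data$group))
}

#' Plot the dysbiosis-diversity curve fit
#'
#' Observations, the selected model's fitted curve, and (for the segmented
#' model) the estimated breakpoint.
#'
#' @param object A `microfam_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microfam_curve <- function(object, ...) {
  fit <- object$models[[object$selected]]
  d <- fit$model
  xv <- d$x
  grid <- data.frame(x = seq(min(xv), max(xv), length.out = 200))
  grid$hinge <- pmax(grid$x - object$breakpoint_estimate, 0)
  grid$y <- predict(fit, grid)
  p <- ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.4) +
    geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    theme_minimal() +
    labs(x = "MD-index", y = "diversity",
         title = paste("selected model:", object$selected))
  if (object$selected == "segmented") {
    p <- p + geom_vline(xintercept = object$breakpoint, linetype = 2)
  }
  p
}

#' Plot a DMM model-selection trace
#'
#' @param object A `microfam_dmm_selection`.
#' @param ... Unused.
#' @return A ggplot of the Laplace criterion (lower is better) over K.
#' @export
autoplot.microfam_dmm_selection <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$k, y = .data$laplace)) +
    geom_line() + geom_point() +
    geom_point(data = dplyr::filter(object$trace, .data$k == object$best_k),
               colour = "firebrick", size = 3) +
    theme_minimal() +
    labs(x = "number of clusters K", y = "Laplace (negative log evidence)")
}

#' Plot a co-abundance network
#'
#' Fruchterman-Reingold layout with edges coloured by interaction sign.
#'
#' @param object A `microfam_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microfam_network <- function(object, seed = 1, ...) {
  g <- object$graph
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$name)],
    y = nodes$y[match(el[, 1], nodes$name)],
    xend = nodes$x[match(el[, 2], nodes$name)],
    yend = nodes$y[match(el[, 2], nodes$name)],
    sign = factor(ifelse(is.na(object$edges$sign) | object$edges$sign >= 0,
                         "positive", "negative"))
  )
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$sign),
                 alpha = 0.6) +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y), size = 2) +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}

#' MD-index by group
#'
#' Violin/box display of per-sample MD-index across diagnosis groups.
#'
#' @param md_tbl Tibble from [md_index()].
#' @param metadata Metadata with `sample_id` and `diagnosis`.
#' @return A ggplot.
#' @export
plot_md_by_group <- function(md_tbl, metadata) {
  d <- dplyr::inner_join(md_tbl, metadata[c("sample_id", "diagnosis")],
                         by = "sample_id")
  ggplot(d, aes(x = .data$diagnosis, y = .data$md)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    theme_minimal() +
    labs(x = NULL, y = "MD-index")
}
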