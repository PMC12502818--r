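# Alpha diversity, dissimilarities and ordination.

#' Per-sample alpha diversity
#'
#' Computes bias-corrected Chao1 richness,
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` with `f1`/`f2` the singleton and
#' doubleton counts, and/or the Shannon numbers equivalent (effective number
#' of taxa), `exp(-sum p_i log p_i)`.
#'
#' @param counts Wide count table or matrix; integer counts are required for
#'   Chao1.
#' @param metrics Any of `"chao1"`, `"shannon_effective"`.
#' @return Tibble with `sample_id` and one column per metric; empty samples
#'   get `NA` with a warning.
#' @export
alpha_diversity <- function(counts, metrics = c("chao1", "shannon_effective")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  m <- count_matrix(counts)
  empty <- rowSums(m) == 0
  if (any(empty)) warn(sprintf("%d empty sample(s): diversity set to NA.", sum(empty)))
  out <- tibble::tibble(sample_id = rownames(m))
  if ("chao1" %in% metrics) {
    if (any(abs(m - round(m)) > 1e-8)) abort("chao1 requires integer counts.")
    out$chao1 <- unname(apply(m, 1, function(x) {
      if (sum(x) == 0) return(NA_real_)
      s_obs <- sum(x > 0)
      f1 <- sum(x == 1); f2 <- sum(x == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    }))
  }
  if ("shannon_effective" %in% metrics) {
    out$shannon_effective <- unname(apply(m, 1, function(x) {
      tot <- sum(x)
      if (tot == 0) return(NA_real_)
      p <- x[x > 0] / tot
      exp(-sum(p * log(p)))
    }))
  }
  out
}

new_microfam_dist <- function(values, metric) {
  stopifnot(isSymmetric(unname(values), tol = 1e-12))
  diag(values) <- 0
  structure(list(values = values, ids = rownames(values), metric = metric),
            class = "microfam_dist")
}

#' @export
print.microfam_dist <- function(x, ...) {
  cat("<microfam_dist> ", x$metric, ", ", nrow(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
as.dist.microfam_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' @export
as.matrix.microfam_dist <- function(x, ...) x$values

#' Pairwise sample dissimilarity
#'
#' Bray-Curtis (`sum|x - y| / sum(x + y)`) on abundances or Jaccard on
#' presence/absence, via vegan.
#'
#' @param table Wide count/abundance table or matrix.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return A `microfam_dist` (symmetric matrix + metric label); coerce with
#'   `as.dist()` or `as.matrix()`. Pairs of all-zero samples are undefined
#'   and returned as `NA` with a warning.
#' @export
dissimilarity <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  m <- count_matrix(table)
  if (nrow(m) < 2) abort("need at least two samples.")
  zero <- rowSums(m) == 0
  d <- if (metric == "bray_curtis") {
    as.matrix(vegan::vegdist(m, method = "bray"))
  } else {
    as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
  }
  if (any(zero)) {
    warn(sprintf("%d all-zero sample(s): pairwise values set to NA.", sum(zero)))
    d[zero, zero] <- NA_real_
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  new_microfam_dist(d, metric)
}

#' Ordination of a distance matrix
#'
#' Principal coordinate analysis (Gower double-centring + eigendecomposition,
#' optional Lingoes correction for negative eigenvalues) or non-metric
#' multidimensional scaling (vegan's monoMDS engine, best of `restarts`
#' random starts).
#'
#' @param d A `microfam_dist`, `dist` or symmetric matrix.
#' @param method `"pcoa"` or `"nmds"`.
#' @param k Number of dimensions (< number of samples).
#' @param lingoes Apply the Lingoes additive correction (PCoA only).
#' @param restarts,max_iter NMDS random restarts and iteration cap.
#' @param seed Optional seed for the NMDS restarts.
#' @return A `microfam_ordination`: `coordinates` tibble (`sample_id`,
#'   `axis1..axisk`), plus `eigenvalues` (PCoA, non-increasing) or `stress`
#'   (NMDS).
#' @export
ordinate <- function(d, method = c("pcoa", "nmds"), k = 2, lingoes = FALSE,
                     restarts = 20, max_iter = 300, seed = NULL) {
  method <- match.arg(method)
  dm <- if (inherits(d, "microfam_dist")) d$values else as.matrix(d)
  n <- nrow(dm)
  if (k >= n) abort("`k` must be smaller than the number of samples.")
  ids <- rownames(dm) %||% paste0("S", seq_len(n))
  if (method == "pcoa") {
    fit <- cmdscale(as.dist(dm), k = k, eig = TRUE, add = lingoes)
    co <- fit$points
    res <- list(method = "pcoa",
                coordinates = coord_tbl(co, ids),
                eigenvalues = fit$eig)
  } else {
    run <- function() vegan::metaMDS(as.dist(dm), k = k, trymax = restarts,
                                     maxit = max_iter, trace = 0,
                                     autotransform = FALSE, wascores = FALSE)
    fit <- if (is.null(seed)) run() else with_seed(seed, run())
    if (!isTRUE(fit$converged)) {
      warn("NMDS did not converge; returning best solution found.")
    }
    res <- list(method = "nmds",
                coordinates = coord_tbl(fit$points, ids),
                stress = fit$stress)
  }
  structure(res, class = "microfam_ordination")
}

coord_tbl <- function(co, ids) {
  colnames(co) <- paste0("axis", seq_len(ncol(co)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(co))
}

#' @export
print.microfam_ordination <- function(x, ...) {
  cat("<microfam_ordination> ", x$method, ", ",
      nrow(x$coordinates), " samples, ",
      ncol(x$coordinates) - 1, " axes", sep = "")
  if (!is.null(x$stress)) cat(", stress ", signif(x$stress, 4), sep = "")
  cat("\n")
  invisible(x)
}
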