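# Co-abundance network inference (CLR + neighborhood selection with
# stability-based penalty choice), node/global statistics, permutation
# nulls, graphlet profiles and between-network distances.

#' Infer a co-abundance network by neighborhood selection
#'
#' CLR-transforms the counts and runs per-taxon sparse (lasso) neighborhood
#' regressions over a shared log-spaced penalty path; the penalty is chosen
#' by stability selection (StARS): over repeated subsamples of size
#' `floor(subsample_ratio * n)`, the densest penalty whose monotonised
#' average edge instability stays at or below `instability` is retained.
#' An edge is kept if selected in either direction (OR rule), with its sign
#' taken from the regression coefficients.
#'
#' @param counts Wide count table or matrix.
#' @param pseudocount CLR pseudocount.
#' @param nlambda,lambda_min_ratio Penalty path settings.
#' @param n_subsamples,subsample_ratio Stability-selection subsamples
#'   (default 50 of 80%).
#' @param instability Target instability (default 0.05).
#' @param seed Seed for the subsampling (mandatory).
#' @return A `microfam_network`: `graph` (igraph), `nodes`, `edges` tibble
#'   (`taxon_a`, `taxon_b`, `sign`, `weight`), `provenance` (settings and
#'   the instability path). Constant taxa are dropped with a warning.
#' @export
infer_network <- function(counts, pseudocount = 0.5, nlambda = 20,
                          lambda_min_ratio = 0.05, n_subsamples = 50,
                          subsample_ratio = 0.8, instability = 0.05, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  X <- value_matrix(clr_transform(counts, pseudocount))
  n <- nrow(X)
  if (n < 50) warn("fewer than 50 samples: network inference will be unstable.")
  const <- apply(X, 2, sd) == 0
  if (any(const)) {
    warn(paste("dropping constant taxa:", paste(colnames(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  p <- ncol(X)
  Xs <- scale(X)
  cmax <- max(abs(cor(Xs)[upper.tri(diag(p))]))
  path <- exp(seq(log(cmax), log(cmax * lambda_min_ratio), length.out = nlambda))

  mb_select <- function(Z) {
    # edge indicator array (upper triangle) per lambda, OR rule
    sel <- array(FALSE, c(p, p, nlambda))
    for (j in seq_len(p)) {
      fit <- glmnet::glmnet(Z[, -j, drop = FALSE], Z[, j], lambda = path,
                            standardize = FALSE)
      B <- as.matrix(fit$beta)
      if (ncol(B) < nlambda) B <- cbind(B, B[, rep(ncol(B), nlambda - ncol(B))])
      nz <- B != 0
      others <- seq_len(p)[-j]
      for (l in seq_len(nlambda)) {
        sel[others[nz[, l]], j, l] <- TRUE
      }
    }
    sel | aperm(sel, c(2, 1, 3))
  }

  up <- upper.tri(matrix(0, p, p))
  freq <- matrix(0, sum(up), nlambda)
  with_seed(seed, {
    for (b in seq_len(n_subsamples)) {
      idx <- sample.int(n, floor(subsample_ratio * n))
      sb <- mb_select(scale(X[idx, , drop = FALSE]))
      freq <- freq + vapply(seq_len(nlambda),
                            function(l) sb[, , l][up], numeric(sum(up)))
    }
  })
  xi <- freq / n_subsamples
  inst <- colMeans(2 * xi * (1 - xi))
  inst_bar <- cummax(inst)
  ok <- which(inst_bar <= instability)
  l_opt <- if (length(ok) > 0) max(ok) else 1

  # final fit on the full data at the selected penalty
  sel_full <- mb_select(Xs)[, , l_opt]
  W <- matrix(0, p, p)
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(Xs[, -j, drop = FALSE], Xs[, j],
                          lambda = path, standardize = FALSE)
    bj <- as.matrix(fit$beta)[, min(l_opt, ncol(as.matrix(fit$beta)))]
    W[seq_len(p)[-j], j] <- bj
  }
  Wsym <- (W + t(W)) / 2
  edges_idx <- which(sel_full & up, arr.ind = TRUE)
  ids <- colnames(X)
  edges <- tibble::tibble(
    taxon_a = ids[edges_idx[, 1]],
    taxon_b = ids[edges_idx[, 2]],
    weight = Wsym[edges_idx],
    sign = sign(Wsym[edges_idx])
  )
  g <- igraph::graph_from_data_frame(
    edges[c("taxon_a", "taxon_b", "weight", "sign")],
    directed = FALSE,
    vertices = data.frame(name = ids))
  structure(list(graph = g, nodes = ids, edges = edges,
                 provenance = list(lambda = path[l_opt], lambda_index = l_opt,
                                   path = path, instability = inst,
                                   target_instability = instability,
                                   n_subsamples = n_subsamples, n = n)),
            class = "microfam_network")
}

#' Wrap an igraph (or edge list) as a microfam network
#'
#' Convenience constructor used by the statistics and distance functions;
#' [infer_network()] produces these directly.
#'
#' @param graph An igraph object (undirected) or a two-column edge data
#'   frame.
#' @param nodes Optional node universe (isolated nodes included).
#' @return A `microfam_network`.
#' @export
as_network <- function(graph, nodes = NULL) {
  if (is.data.frame(graph)) {
    nodes <- nodes %||% sort(unique(c(graph[[1]], graph[[2]])))
    graph <- igraph::graph_from_data_frame(graph, directed = FALSE,
                                           vertices = data.frame(name = nodes))
  }
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph)
  graph <- igraph::simplify(graph)
  el <- igraph::as_edgelist(graph)
  structure(list(graph = graph, nodes = igraph::V(graph)$name,
                 edges = tibble::tibble(taxon_a = el[, 1], taxon_b = el[, 2],
                                        weight = NA_real_, sign = NA_real_),
                 provenance = list()),
            class = "microfam_network")
}

#' @export
print.microfam_network <- function(x, ...) {
  cat("<microfam_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Node centralities
#'
#' Degree, betweenness, PageRank (damping 0.85), eigenvector centrality and
#' mean neighbour degree (knn) on the unweighted undirected skeleton.
#' Isolated nodes receive zeros.
#'
#' @param net A `microfam_network` or igraph object.
#' @return Tibble `taxon_id`, `degree`, `betweenness`, `pagerank`,
#'   `eigenvector`, `knn_degree`.
#' @export
node_centralities <- function(net) {
  g <- if (inherits(net, "microfam_network")) net$graph else net
  if (igraph::vcount(g) == 0) abort("the graph has no nodes.")
  deg <- igraph::degree(g)
  kn <- suppressWarnings(igraph::knn(g)$knn)
  kn[!is.finite(kn)] <- 0
  ev <- if (igraph::ecount(g) == 0) rep(0, igraph::vcount(g)) else
    igraph::eigen_centrality(g)$vector
  tibble::tibble(
    taxon_id = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
    degree = unname(deg),
    betweenness = unname(igraph::betweenness(g)),
    pagerank = unname(igraph::page_rank(g, damping = 0.85)$vector),
    eigenvector = unname(ev),
    knn_degree = unname(kn)
  )
}

#' Permutation null test for node centralities
#'
#' Compares observed node centralities against an ensemble of
#' degree-preserving rewirings (double-edge swaps) of the same graph via
#' one-sided Z-tests (`Z = (obs - mean_null) / sd_null`; upper-tail p).
#' Graphs too sparse to rewire fall back to an Erdos-Renyi ensemble with
#' matching node and edge counts, with a warning. Optionally the observed
#' centrality is averaged over edge subsamples.
#'
#' @param net A `microfam_network` or igraph.
#' @param metric One of `degree`, `betweenness`, `pagerank`, `eigenvector`,
#'   `knn_degree`.
#' @param n_perm Size of the null ensemble (study convention 10000).
#' @param seed Seed (mandatory).
#' @param null `"degree_preserving"` (default) conditions on the degree
#'   sequence and asks whether a node is more central than its degree
#'   alone implies; `"erdos_renyi"` only conditions on the edge count, so
#'   high-degree hubs themselves stand out.
#' @param obs_subsamples If > 0, average the observed centrality over this
#'   many random 80%-edge subgraphs instead of the single full graph.
#' @return Tibble `taxon_id`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_value` (one-sided upper; `NA` where the null sd is zero, flagged in
#'   `degenerate`).
#' @export
centrality_null_test <- function(net, metric = "betweenness", n_perm = 1000,
                                 seed, null = c("degree_preserving", "erdos_renyi"),
                                 obs_subsamples = 0) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  null <- match.arg(null)
  g <- if (inherits(net, "microfam_network")) net$graph else net
  m <- igraph::ecount(g); nv <- igraph::vcount(g)
  cent <- function(gr) node_centralities(gr)[[metric]]
  rewirable <- null == "degree_preserving" && m >= 2
  if (null == "degree_preserving" && m < 2) {
    warn("graph too sparse to rewire; using an Erdos-Renyi ensemble.")
  }
  with_seed(seed, {
    obs <- if (obs_subsamples > 0) {
      Reduce(`+`, lapply(seq_len(obs_subsamples), function(i) {
        keep <- sample.int(m, floor(0.8 * m))
        cent(igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE))
      })) / obs_subsamples
    } else cent(g)
    null_mat <- vapply(seq_len(n_perm), function(i) {
      gp <- if (rewirable) {
        igraph::rewire(g, igraph::keeping_degseq(niter = max(10 * m, 100)))
      } else {
        igraph::sample_gnm(nv, m)
      }
      cent(gp)
    }, numeric(nv))
  })
  mu <- rowMeans(null_mat)
  sdv <- apply(null_mat, 1, sd)
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA_real_
  tibble::tibble(
    taxon_id = igraph::V(g)$name %||% as.character(seq_len(nv)),
    observed = obs, null_mean = mu, null_sd = sdv, z = z,
    p_value = pnorm(z, lower.tail = FALSE),
    degenerate = sdv == 0
  )
}

#' Global network statistics
#'
#' Degree assortativity, diameter and radius (on the largest connected
#' component), node and edge counts, density, global clustering
#' coefficient, and natural connectivity
#' `ln((1/n) sum_i exp(lambda_i))` over the full adjacency spectrum.
#'
#' @param net A `microfam_network` or igraph.
#' @return One-row tibble.
#' @export
global_network_stats <- function(net) {
  g <- if (inherits(net, "microfam_network")) net$graph else net
  nv <- igraph::vcount(g); m <- igraph::ecount(g)
  if (nv == 0) {
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L, density = 0,
                          clustering = 0, assortativity = NA_real_,
                          diameter = NA_real_, radius = NA_real_,
                          natural_connectivity = 0))
  }
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  nc <- matrixStats_logsumexp(ev) - log(nv)
  tibble::tibble(
    n_nodes = nv, n_edges = m,
    density = igraph::edge_density(g),
    clustering = ifelse(m == 0, 0, igraph::transitivity(g, type = "global")),
    assortativity = suppressWarnings(igraph::assortativity_degree(g)),
    diameter = igraph::diameter(giant),
    radius = igraph::radius(giant),
    natural_connectivity = nc
  )
}

matrixStats_logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Graphlet profile (connected 2-4-node induced subgraphs)
#'
#' Exact counts of the nine connected graphlets on 2-4 nodes via closed
#' combinatorial formulas: G0 edge, G1 3-path, G2 triangle, G3 4-path,
#' G4 3-star (claw), G5 4-cycle, G6 paw (triangle + pendant), G7 diamond
#' (K4 minus an edge), G8 K4. Non-induced counts are computed from the
#' adjacency algebra and converted to induced counts by subtracting the
#' containment multiplicities.
#'
#' @param net A `microfam_network` or igraph.
#' @return Tibble `graphlet` (G0-G8), `label`, `count`.
#' @export
graphlet_profile <- function(net) {
  g <- if (inherits(net, "microfam_network")) net$graph else net
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  n <- nrow(A)
  d <- rowSums(A)
  m <- sum(d) / 2
  A2 <- A %*% A
  tri_v <- rowSums(A2 * A) / 2        # triangles through each vertex
  t3 <- sum(tri_v) / 3                # triangles
  p2 <- sum(choose(d, 2))             # non-induced 3-paths

  el <- igraph::as_edgelist(g, names = FALSE)
  k_uv <- if (m > 0) A2[el] else numeric(0)      # common neighbors per edge
  du <- d[el[, 1]]; dv <- d[el[, 2]]

  claw_n <- sum(choose(d, 3))
  p4_n <- if (m > 0) sum((du - 1) * (dv - 1)) - 3 * t3 else 0
  c4_n <- (sum(A2^2) - 2 * m - 2 * sum(d * (d - 1))) / 8
  paw_n <- sum(tri_v * (d - 2))
  diamond_n <- sum(choose(k_uv, 2))
  k4 <- 0
  if (m > 0) {
    for (e in seq_len(nrow(el))) {
      if (k_uv[e] >= 2) {
        common <- which(A[el[e, 1], ] == 1 & A[el[e, 2], ] == 1)
        k4 <- k4 + sum(A[common, common]) / 2
      }
    }
    k4 <- k4 / 6
  }

  g7 <- diamond_n - 6 * k4
  g5 <- c4_n - g7 - 3 * k4
  g6 <- paw_n - 4 * g7 - 12 * k4
  g4 <- claw_n - g6 - 2 * g7 - 4 * k4
  g3 <- p4_n - 2 * g6 - 4 * g5 - 6 * g7 - 12 * k4

  tibble::tibble(
    graphlet = paste0("G", 0:8),
    label = c("edge", "path-3", "triangle", "path-4", "claw", "cycle-4",
              "paw", "diamond", "K4"),
    count = c(m, p2 - 3 * t3, t3, g3, g4, g5, g6, g7, k4)
  )
}

#' Distances between co-abundance networks
#'
#' `graphlet_correlation`: one minus the Spearman correlation of the
#' normalised graphlet frequency vectors. `edge_sharing`: one minus the
#' Jaccard index of the edge sets (networks must share a node universe).
#'
#' @param nets Named list of `microfam_network`/igraph objects.
#' @param metric `"graphlet_correlation"` or `"edge_sharing"`.
#' @return A `microfam_dist` over the networks; pairs undefined because of
#'   an all-zero graphlet vector are `NA` with a warning.
#' @export
network_distance <- function(nets, metric = c("graphlet_correlation", "edge_sharing")) {
  metric <- match.arg(metric)
  if (length(nets) < 2) abort("need at least two networks.")
  nm <- names(nets) %||% paste0("net", seq_along(nets))
  k <- length(nets)
  D <- matrix(0, k, k, dimnames = list(nm, nm))
  if (metric == "graphlet_correlation") {
    profs <- lapply(nets, function(x) {
      ct <- graphlet_profile(x)$count
      if (sum(ct) == 0) return(rep(NA_real_, length(ct)))
      ct / sum(ct)
    })
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (anyNA(profs[[i]]) || anyNA(profs[[j]])) {
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- 1 - cor(profs[[i]], profs[[j]], method = "spearman")
      }
    }
    if (anyNA(D)) warn("all-zero graphlet vector(s): undefined pairs set to NA.")
  } else {
    sets <- lapply(nets, function(x) {
      ed <- if (inherits(x, "microfam_network")) x$edges[1:2] else {
        el <- igraph::as_edgelist(x); tibble::tibble(a = el[, 1], b = el[, 2])
      }
      if (nrow(ed) == 0) return(character(0))
      apply(ed, 1, function(r) paste(sort(r), collapse = "|"))
    })
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      u <- union(sets[[i]], sets[[j]])
      D[i, j] <- D[j, i] <- if (length(u) == 0) 0 else
        1 - length(intersect(sets[[i]], sets[[j]])) / length(u)
    }
  }
  new_microfam_dist(D, paste0(metric))
}
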