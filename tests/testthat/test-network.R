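test_that("graphlet counts equal brute-force enumeration on canonical and random graphs", {
  # triangle
  tri <- graph_of(random_graph(3, 0) + outer(1:3, 1:3, function(i, j) as.numeric(i != j)))
  expect_equal(graphlet_profile(tri)$count, c(3, 0, 1, rep(0, 6)))
  # path P4
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 3] <- A[3, 4] <- 1; A <- A + t(A)
  expect_equal(graphlet_profile(graph_of(A))$count, c(3, 2, 0, 1, rep(0, 5)))
  # K4
  K4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(graphlet_profile(graph_of(K4))$count,
               c(6, 0, 4, 0, 0, 0, 0, 0, 1))
  # random graphs up to 30 nodes vs the brute-force oracle
  set.seed(71)
  for (i in 1:6) {
    n <- sample(c(8, 12, 20, 30), 1)
    A <- random_graph(n, runif(1, 0.08, 0.35))
    expect_equal(graphlet_profile(graph_of(A))$count,
                 unname(brute_graphlets(A)))
  }
})

test_that("natural connectivity matches its spectral definition and grows with edges", {
  # empty graph: all eigenvalues 0 -> ln(mean(exp(0))) = 0
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(global_network_stats(empty)$natural_connectivity, 0)
  # complete graph: closed form from eigenvalues (n-1, -1, ..., -1)
  n <- 6
  kn <- igraph::make_full_graph(n)
  st <- global_network_stats(kn)
  expect_equal(st$natural_connectivity,
               log((exp(n - 1) + (n - 1) * exp(-1)) / n), tolerance = 1e-10)
  expect_equal(st$density, 1)
  expect_equal(st$clustering, 1)
  # exhaustive edge-monotonicity on all 5-node graphs
  pairs <- t(combn(5, 2))
  n_pairs <- nrow(pairs)
  nc <- vapply(0:(2^n_pairs - 1), function(code) {
    A <- matrix(0, 5, 5)
    on <- which(bitwAnd(code, 2^(seq_len(n_pairs) - 1)) > 0)
    for (e in on) A[pairs[e, 1], pairs[e, 2]] <- A[pairs[e, 2], pairs[e, 1]] <- 1
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    log(mean(exp(ev)))
  }, 0)
  ok <- TRUE
  for (code in 0:(2^n_pairs - 1)) {
    absent <- which(bitwAnd(code, 2^(seq_len(n_pairs) - 1)) == 0)
    for (e in absent) {
      if (nc[code + 2^(e - 1) + 1] <= nc[code + 1]) ok <- FALSE
    }
  }
  expect_true(ok)
})

test_that("node centralities match closed forms on stars and cycles", {
  star <- igraph::make_star(8, mode = "undirected")
  ct <- node_centralities(star)
  hub <- which.max(ct$degree)
  expect_equal(ct$degree[hub], 7)
  expect_equal(ct$betweenness[hub], 7 * 6 / 2)
  expect_equal(sum(ct$pagerank), 1, tolerance = 1e-9)
  cyc <- node_centralities(igraph::make_ring(7))
  expect_true(all(abs(cyc$degree - 2) < 1e-12))
  expect_lt(diff(range(cyc$betweenness)), 1e-9)
  expect_lt(diff(range(cyc$eigenvector)), 1e-9)
})

test_that("degree-preserving nulls keep degrees and expose planted hubs", {
  set.seed(72)
  A <- random_graph(25, 0.15)
  # plant a hub connected to everything
  A[1, ] <- 1; A[, 1] <- 1; diag(A) <- 0
  g <- graph_of(A)
  # the hub stands out against an edge-count-only null
  res <- centrality_null_test(g, metric = "betweenness", n_perm = 200,
                              seed = 73, null = "erdos_renyi")
  expect_equal(which.max(res$z), 1)
  # conditioned on its degree, the same hub is unremarkable
  resdp <- centrality_null_test(g, metric = "betweenness", n_perm = 200, seed = 73)
  expect_lt(res$p_value[1], 0.05)
  expect_gt(resdp$p_value[1], 0.05)
  # rewired ensembles preserve every degree: degree z-scores are all NA/0
  resd <- centrality_null_test(g, metric = "degree", n_perm = 100, seed = 74)
  expect_true(all(resd$degenerate))
  expect_true(all(is.na(resd$z)))
  expect_warning(
    centrality_null_test(igraph::make_empty_graph(4, directed = FALSE) |>
                           igraph::add_edges(c(1, 2)),
                         n_perm = 100, seed = 75),
    "sparse")
})

test_that("network distances satisfy their endpoint identities", {
  set.seed(76)
  A <- random_graph(12, 0.3)
  g1 <- graph_of(A)
  # isomorphic copy: permuted labels
  p <- sample(12)
  B <- A[p, p]
  dimnames(B) <- dimnames(A)
  g2 <- graph_of(B)
  g3 <- graph_of(random_graph(12, 0.3))
  d <- network_distance(list(a = g1, b = g2, c = g3), "graphlet_correlation")
  expect_equal(as.matrix(d)["a", "b"], 0, tolerance = 1e-12)
  expect_true(isSymmetric(as.matrix(d)))
  expect_equal(diag(as.matrix(d)), setNames(rep(0, 3), c("a", "b", "c")))
  # edge sharing: identical -> 0, disjoint -> 1
  e1 <- igraph::make_graph(c("x", "y", "y", "z"), directed = FALSE)
  e2 <- igraph::make_graph(c("x", "y", "y", "z"), directed = FALSE)
  e3 <- igraph::make_graph(c("x", "w", "w", "v"), directed = FALSE)
  de <- network_distance(list(p = e1, q = e2, r = e3), "edge_sharing")
  expect_equal(as.matrix(de)["p", "q"], 0)
  expect_equal(as.matrix(de)["p", "r"], 1)
})

test_that("independent taxa give sparse networks and planted couplings are found", {
  cfg0 <- simulation_config(n_families = 60, family_templates = c(quad = 1),
                            n_taxa = 25, disease_log2fc = rep(0, 25),
                            dispersion_inflation_ibd = 1,
                            heritable_taxa = setNames(numeric(0), character(0)),
                            seed = 77)
  co0 <- simulate_cohort(cfg0)
  net0 <- infer_network(co0$counts, n_subsamples = 20, seed = 78)
  dens0 <- nrow(net0$edges) / choose(25, 2)
  expect_lt(dens0, 0.05)
  # adjacency is symmetric with zero diagonal by construction
  Adj <- igraph::as_adjacency_matrix(net0$graph, sparse = FALSE)
  expect_true(isSymmetric(Adj))
  expect_true(all(diag(Adj) == 0))

  couple <- tibble::tibble(taxon_a = "ASV_0005", taxon_b = "ASV_0012",
                           rho = 0.8, condition = "all")
  cfg1 <- simulation_config(n_families = 60, family_templates = c(quad = 1),
                            n_taxa = 25, disease_log2fc = rep(0, 25),
                            dispersion_inflation_ibd = 1, couplings = couple,
                            heritable_taxa = setNames(numeric(0), character(0)),
                            seed = 79)
  co1 <- simulate_cohort(cfg1)
  net1 <- infer_network(co1$counts, n_subsamples = 20, seed = 80)
  hit <- any((net1$edges$taxon_a == "ASV_0005" & net1$edges$taxon_b == "ASV_0012") |
               (net1$edges$taxon_a == "ASV_0012" & net1$edges$taxon_b == "ASV_0005"))
  expect_true(hit)
})
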