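test_that("alpha diversity matches the plug-in formulas", {
  # no singletons/doubletons -> chao1 = S_obs
  m <- rbind(S1 = c(10, 5, 3, 0), S2 = c(4, 4, 4, 4))
  colnames(m) <- paste0("T", 1:4)
  a <- alpha_diversity(m)
  expect_equal(a$chao1[1], 3)
  # f1 = 2, f2 = 0, S_obs = 2 -> chao1 = 2 + 2*1/2 = 3
  m2 <- rbind(S1 = c(1, 1, 0))
  colnames(m2) <- paste0("T", 1:3)
  expect_equal(alpha_diversity(m2)$chao1, 3)
  # uniform abundance over k taxa -> effective Shannon = k
  expect_equal(a$shannon_effective[2], 4)
  # agrees with vegan where the conventions coincide (bias-corrected case)
  set.seed(4)
  mm <- matrix(rpois(120, 3), 4, 30, dimnames = list(paste0("S", 1:4), paste0("T", 1:30)))
  ours <- alpha_diversity(mm)$shannon_effective
  expect_equal(ours, unname(exp(vegan::diversity(mm))), tolerance = 1e-12)
  # empty sample flagged NA
  m3 <- rbind(S1 = c(0, 0), S2 = c(1, 2))
  colnames(m3) <- c("T1", "T2")
  expect_warning(a3 <- alpha_diversity(m3), "empty")
  expect_true(is.na(a3$chao1[1]))
})

test_that("dissimilarities match closed forms and vegan", {
  m <- rbind(x = c(2, 0), y = c(1, 1), z = c(2, 0))
  colnames(m) <- c("T1", "T2")
  d <- as.matrix(dissimilarity(m, "bray_curtis"))
  expect_equal(d["x", "y"], 0.5)          # (1+1)/4
  expect_equal(d["x", "z"], 0)            # identical samples
  disj <- rbind(a = c(3, 0), b = c(0, 5))
  colnames(disj) <- c("T1", "T2")
  expect_equal(as.matrix(dissimilarity(disj))["a", "b"], 1)
  j <- as.matrix(dissimilarity(m, "jaccard"))
  expect_equal(j["x", "y"], 0.5)          # shared {T1} of {T1, T2}
  # permutation equivariance in sample order
  set.seed(5)
  mm <- matrix(rpois(50, 8), 5, 10, dimnames = list(paste0("S", 1:5), paste0("T", 1:10)))
  p <- sample(5)
  d1 <- as.matrix(dissimilarity(mm))[p, p]
  d2 <- as.matrix(dissimilarity(mm[p, ]))
  expect_equal(d1, d2)
})

test_that("PCoA recovers planar configurations and orders eigenvalues", {
  set.seed(6)
  pts <- cbind(rnorm(12), rnorm(12))
  rownames(pts) <- paste0("S", 1:12)
  d <- as.matrix(dist(pts))
  ord <- ordinate(d, "pcoa", k = 2)
  co <- as.matrix(ord$coordinates[, -1])
  pro <- vegan::procrustes(pts, co)
  expect_lt(sum(pro$residuals^2), 1e-6)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))
})

test_that("NMDS reaches near-zero stress on perfectly 2-embeddable distances", {
  set.seed(7)
  pts <- cbind(runif(15, 0, 4), runif(15, 0, 4))
  rownames(pts) <- paste0("S", 1:15)
  d <- as.matrix(dist(pts))
  ord <- suppressWarnings(ordinate(d, "nmds", k = 2, restarts = 10, seed = 8))
  expect_lt(ord$stress, 0.01)
})

test_that("PERMANOVA reproduces classical ANOVA on univariate Euclidean data", {
  set.seed(8)
  y <- rnorm(30) + rep(c(0, 0.8, 0.2), each = 10)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  md <- data.frame(sample_id = paste0("S", 1:30), g = g)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(md$sample_id, md$sample_id)
  pm <- permanova(d, md, ~ g, n_perm = 99, seed = 1)
  f_classic <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(pm$terms$pseudo_F[1], f_classic, tolerance = 1e-10)
  # single-term R2 identity
  tt <- pm$terms
  expect_equal(tt$R2[1], 1 - tt$sum_of_squares[2] / tt$sum_of_squares[3])
})

test_that("PERMANOVA agrees with the independent vegan implementation", {
  set.seed(9)
  mm <- matrix(rpois(200, 10), 20, 10,
               dimnames = list(paste0("S", 1:20), paste0("T", 1:10)))
  md <- data.frame(sample_id = paste0("S", 1:20),
                   g = factor(rep(c("a", "b"), 10)),
                   x = rnorm(20))
  d <- dissimilarity(mm)
  ours <- permanova(d, md, ~ x + g, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(d) ~ x + g, data = md, permutations = 99,
                        by = "terms")
  expect_equal(ours$terms$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
  expect_equal(ours$terms$sum_of_squares[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(ours$terms$R2[1:2], ref$R2[1:2], tolerance = 1e-8)
})

test_that("sequential sums of squares always add to the total", {
  set.seed(10)
  mm <- matrix(rpois(300, 10), 30, 10,
               dimnames = list(paste0("S", 1:30), paste0("T", 1:10)))
  md <- data.frame(sample_id = paste0("S", 1:30),
                   g = factor(rep(c("a", "b", "c"), 10)), x = rnorm(30))
  d <- dissimilarity(mm)
  for (f in list(~ g + x, ~ x + g)) {
    pm <- permanova(d, md, f, n_perm = 19, seed = 3)
    tt <- pm$terms
    expect_equal(sum(tt$sum_of_squares[tt$term != "Total"]),
                 tt$sum_of_squares[tt$term == "Total"], tolerance = 1e-8)
  }
})

test_that("strongly separated clusters reach the minimal permutation p", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 30, 0.1), 10))
  rownames(pts) <- paste0("S", 1:20)
  md <- data.frame(sample_id = rownames(pts), g = factor(rep(c("a", "b"), each = 10)))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(rownames(pts), rownames(pts))
  pm <- permanova(d, md, ~ g, n_perm = 199, seed = 4)
  expect_equal(pm$terms$p_perm[1], 1 / 200)
})

test_that("conditioning removes a confounder's contribution before testing", {
  set.seed(12)
  n <- 40
  z <- rnorm(n)
  g <- factor(rep(c("a", "b"), each = n / 2))
  y <- cbind(z + rnorm(n, 0, 0.2), z + rnorm(n, 0, 0.2))
  rownames(y) <- paste0("S", 1:n)
  md <- data.frame(sample_id = rownames(y), g = g, z = z)
  d <- as.matrix(dist(y)); dimnames(d) <- list(rownames(y), rownames(y))
  pm <- permanova(d, md, ~ g, condition = ~ z, n_perm = 99, seed = 5)
  expect_gt(pm$terms$p_perm[1], 0.05)
  expect_gt(pm$ss_condition, pm$terms$sum_of_squares[1])
})

test_that("rank-deficient designs raise an error naming the aliased term", {
  set.seed(13)
  mm <- matrix(rpois(100, 10), 10, 10,
               dimnames = list(paste0("S", 1:10), paste0("T", 1:10)))
  g <- factor(rep(c("a", "b"), 5))
  md <- data.frame(sample_id = paste0("S", 1:10), g = g, g2 = g)
  expect_error(permanova(dissimilarity(mm), md, ~ g + g2, n_perm = 19),
               "aliased")
})

test_that("dispersion test flags unequal spread and excludes singleton groups", {
  set.seed(14)
  pts <- rbind(matrix(rnorm(60, 0, 1), 30), matrix(rnorm(60, 0, 4), 30))
  rownames(pts) <- paste0("S", 1:60)
  d <- as.matrix(dist(pts)); dimnames(d) <- list(rownames(pts), rownames(pts))
  g <- rep(c("tight", "wide"), each = 30)
  res <- dispersion_test(d, g, n_perm = 199, seed = 6)
  expect_lt(res$p_perm, 0.05)
  expect_true(all(res$distances$distance_to_centroid >= 0))
  expect_gt(mean(res$distances$distance_to_centroid[res$distances$group == "wide"]),
            mean(res$distances$distance_to_centroid[res$distances$group == "tight"]))
  # singleton group excluded with warning
  g2 <- c(g[-1], "lonely")
  expect_warning(dispersion_test(d, g2, n_perm = 99, seed = 7), "size 1")
})
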