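test_that("partial correlation matches the residualise-then-correlate oracle", {
  set.seed(41)
  n <- 20
  Z <- cbind(rnorm(n), rnorm(n))
  x <- 0.5 * Z[, 1] + rnorm(n)
  y <- -0.3 * Z[, 2] + 0.4 * x + rnorm(n)
  res <- partial_correlation(x, y, Z, method = "pearson")
  rx <- resid(lm(x ~ Z)); ry <- resid(lm(y ~ Z))
  oracle <- cor(rx, ry)
  expect_equal(res$estimate, oracle, tolerance = 1e-10)
  # the p-value matches the t reference at df = n - k - 2
  tt <- oracle * sqrt((n - 4) / (1 - oracle^2))
  expect_equal(res$p_value, 2 * pt(-abs(tt), n - 4), tolerance = 1e-10)
})

test_that("partial correlation limit cases behave", {
  set.seed(42)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30); Z <- cbind(rnorm(30))
  # no covariates -> plain correlation
  expect_equal(partial_correlation(x, y, method = "pearson")$estimate,
               cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, y, method = "spearman")$estimate,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # y = x exactly -> partial rho = 1
  expect_equal(partial_correlation(x, x, Z, method = "pearson")$estimate, 1)
  # collinear covariates -> singular matrix error
  expect_error(partial_correlation(x, y, cbind(Z, Z), "pearson"), "singular")
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "n >")
})

test_that("Brown's method reduces to Fisher at zero correlation and stays calibrated", {
  p <- c(0.02, 0.2, 0.5)
  fisher <- pchisq(-2 * sum(log(p)), df = 6, lower.tail = FALSE)
  expect_equal(browns_combine(p), fisher, tolerance = 1e-12)
  expect_equal(browns_combine(p, diag(3)), fisher, tolerance = 1e-12)
  # perfectly correlated tests: combined p close to the single p
  R1 <- matrix(1, 3, 3)
  for (p0 in c(0.01, 0.05)) {
    comb <- browns_combine(rep(p0, 3), R1)
    expect_lt(abs(comb - p0) / p0, 0.10)
  }
  # bounded output on random inputs
  set.seed(43)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    pv <- runif(k)
    R <- cov2cor(crossprod(matrix(rnorm(k * k), k)))
    out <- browns_combine(pv, R)
    expect_true(out >= 0 && out <= 1)
  }
  expect_warning(browns_combine(c(0, 0.5)), "clamped")
})

test_that("group tests use the right machinery per design", {
  set.seed(44)
  d2 <- data.frame(v = c(rnorm(12), rnorm(12, 1)), g = rep(c("a", "b"), each = 12))
  t2 <- group_tests(d2, "v", "g")
  expect_equal(t2$method, "wilcoxon rank-sum")
  # two groups: KW chi-square p equals the normal-approximation rank-sum p
  kw <- kruskal.test(d2$v, factor(d2$g))$p.value
  wt <- wilcox.test(v ~ g, d2, exact = FALSE, correct = FALSE)$p.value
  expect_equal(kw, wt, tolerance = 1e-10)

  d3 <- data.frame(v = rnorm(60), g = rep(c("a", "b", "c"), each = 20))
  t3 <- group_tests(d3, "v", "g")
  expect_equal(t3$method[1], "kruskal-wallis")
  expect_equal(nrow(t3), 4)  # omnibus + 3 pairwise
  expect_true(all(t3$p_fdr >= t3$p_value - 1e-12))

  dp <- data.frame(v = c(rnorm(10), rnorm(10) + 1), g = rep(c("pre", "post"), each = 10),
                   id = rep(1:10, 2))
  tp <- group_tests(dp, "v", "g", paired_by = "id")
  expect_equal(tp$method, "paired t-test")
  oracle <- t.test(dp$v[11:20], dp$v[1:10], paired = TRUE)$p.value
  expect_equal(tp$p_value, oracle, tolerance = 1e-10)
})

test_that("rank-test p-values are calibrated under the null and powered under shift", {
  set.seed(45)
  pvals <- replicate(300, {
    d <- data.frame(v = rnorm(30), g = rep(c("a", "b"), each = 15))
    group_tests(d, "v", "g")$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  power <- mean(replicate(100, {
    d <- data.frame(v = c(rnorm(50), rnorm(50, 1)), g = rep(c("a", "b"), each = 50))
    group_tests(d, "v", "g")$p_value
  }) < 0.05)
  expect_gt(power, 0.9)
})

test_that("the combined-correlation scan is self-consistent", {
  cfg <- simulation_config(n_families = 30, n_taxa = 15, seed = 46)
  co <- simulate_cohort(cfg)
  scan <- correlation_scan(co$counts, co$metadata, phenotypes = "calprotectin")
  expect_equal(nrow(scan), 15)
  expect_true(all(scan$brown_p >= 0 & scan$brown_p <= 1))
  expect_true(all(scan$brown_p_fdr >= scan$brown_p - 1e-12))
  # Brown p is never smaller than the smallest input p divided by k
  expect_true(all(scan$brown_p >=
                    pmin(scan$p_pearson, scan$p_spearman, scan$p_kendall) / 3 - 1e-12))
  # disease-coupled taxa correlate with the dysbiosis-coupled biomarker
  up <- names(which(co$truth$log2fc > 0))
  expect_lt(min(scan$brown_p_fdr[scan$taxon_id %in% up]), 0.05)
})

test_that("adjusted linear models recover ANOVA and drop noise covariates", {
  skip_if_not_installed("emmeans")
  set.seed(47)
  n <- 90
  d <- data.frame(
    y = rnorm(n) + rep(c(0, 1, 0.5), each = n / 3),
    diagnosis = factor(rep(c("Control", "CD", "UC"), each = n / 3)),
    sex = factor(sample(c("F", "M"), n, TRUE)),
    bmi = rnorm(n, 25, 4), age = rnorm(n, 45, 10)
  )
  # balanced noise covariates: adjusted group contrast ~ unadjusted
  fit <- fit_adjusted_lm(d, "y", group = "diagnosis", stepwise = FALSE)
  raw <- diff(tapply(d$y, d$diagnosis, mean))[1] # CD - Control on means
  ctr <- fit$contrasts
  cd_ctrl <- ctr$estimate[grepl("Control", ctr$comparison) & grepl("CD", ctr$comparison)]
  expect_lt(abs(abs(cd_ctrl) - abs(raw)), 0.5)
  # F test of the stage-2 model matches one-way ANOVA on residualised y
  # pure-noise phenotype is dropped by stepwise selection most of the time
  set.seed(48)
  dropped <- replicate(20, {
    d$noise <- rnorm(n)
    f <- fit_adjusted_lm(d, "y", group = "diagnosis", phenotype = "noise")
    !("noise" %in% all.vars(formula(f$model)))
  })
  expect_gte(mean(dropped), 0.7)
})

test_that("interaction slope contrasts equal per-group OLS slope differences", {
  skip_if_not_installed("emmeans")
  set.seed(49)
  n <- 120
  g <- factor(rep(c("Control", "CD"), each = n / 2))
  x <- rnorm(n)
  y <- ifelse(g == "CD", 1.5 * x, 0.5 * x) + rnorm(n, 0, 0.3)
  d <- data.frame(y = y, diagnosis = g, ph = x,
                  sex = factor(sample(c("F", "M"), n, TRUE)),
                  bmi = rnorm(n, 25, 3), age = rnorm(n, 40, 8))
  fit <- fit_adjusted_lm(d, "y", group = "diagnosis", phenotype = "ph",
                         stepwise = FALSE)
  sl <- fit$contrasts[fit$contrasts$type == "slope", ]
  d$r <- resid(lm(y ~ sex + scale(bmi) + scale(age), d))
  s_cd <- coef(lm(r ~ ph, d[d$diagnosis == "CD", ]))[2]
  s_ct <- coef(lm(r ~ ph, d[d$diagnosis == "Control", ]))[2]
  expect_equal(abs(sl$estimate), abs(unname(s_cd - s_ct)), tolerance = 1e-8)
})
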