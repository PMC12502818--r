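mk_results <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(taxon_id = r[[1]], base_mean = 10,
                   log2_fold_change = as.numeric(r[[2]]), lfc_se = 0.1,
                   wald_stat = 1, p_value = as.numeric(r[[3]]),
                   p_fdr = as.numeric(r[[3]]), contrast = r[[4]])
  }))
}

test_that("MD taxon sets follow the either-contrast rule with disjointness", {
  res <- mk_results(
    list("up_cd", 1.5, 0.01, "CD_vs_Control"),
    list("up_cd", 0.2, 0.50, "UC_vs_Control"),
    list("dn_uc", -0.1, 0.80, "CD_vs_Control"),
    list("dn_uc", -2.0, 0.001, "UC_vs_Control"),
    list("conflict", 1.2, 0.01, "CD_vs_Control"),
    list("conflict", -1.2, 0.01, "UC_vs_Control"),
    list("ns", 3.0, 0.90, "CD_vs_Control"))
  expect_warning(sets <- derive_md_taxa(res), "opposite")
  expect_equal(sets$ibd_up, "up_cd")      # significant in CD only is enough
  expect_equal(sets$control_up, "dn_uc")
  expect_false("conflict" %in% c(sets$ibd_up, sets$control_up))
  expect_false("ns" %in% sets$ibd_up)
  # no significant taxa -> both sets empty
  empty <- derive_md_taxa(mk_results(list("a", 1, 0.9, "CD_vs_Control")))
  expect_length(empty$ibd_up, 0)
  expect_length(empty$control_up, 0)
})

test_that("the MD-index matches its closed form and flags zero denominators", {
  sets <- structure(list(ibd_up = c("d1", "d2"), control_up = c("h1", "h2"),
                         source = list()), class = "microfam_mdsets")
  m <- rbind(S1 = c(d1 = 5, d2 = 4, h1 = 50, h2 = 49),
             S2 = c(d1 = 3, d2 = 3, h1 = 3, h2 = 3),
             S3 = c(d1 = 9, d2 = 0, h1 = 0, h2 = 0))
  md <- suppressWarnings(md_index(m, sets, basis = "relative"))
  # relative abundances: S2 numerator sum = denominator sum -> MD = 1
  expect_equal(md$md[2], 1)
  expect_true(is.na(md$md[3]))            # zero denominator -> missing
  expect_equal(attr(md, "n_undefined"), 1)
  # raw closed form on normalized basis with equal size factors
  m2 <- rbind(S1 = c(d1 = 9, d2 = 0, h1 = 99, h2 = 0),
              S2 = c(d1 = 9, d2 = 0, h1 = 99, h2 = 0))
  md2 <- md_index(m2, sets, basis = "normalized")
  expect_equal(md2$md[1], log1p(9) / log1p(99))
  expect_equal(md2$md[1], 0.5)            # ln 10 / ln 100
  # missing taxa are an error
  expect_error(md_index(m[, 1:3], sets, basis = "relative"), "absent")
})

test_that("the MD-index is monotone in each set's abundances", {
  sets <- structure(list(ibd_up = c("d1", "d2"), control_up = c("h1", "h2"),
                         source = list()), class = "microfam_mdsets")
  base <- c(d1 = 5, d2 = 2, h1 = 20, h2 = 10)
  md_of <- function(x) md_index(rbind(S1 = x, S2 = x), sets, basis = "normalized")$md[1]
  m0 <- md_of(base)
  up <- base; up["d1"] <- up["d1"] + 5
  dn <- base; dn["h2"] <- dn["h2"] + 5
  expect_gt(md_of(up), m0)
  expect_lt(md_of(dn), m0)
  # permutation of taxa within sets leaves MD unchanged
  perm <- base[c("d2", "d1", "h2", "h1")]
  names(perm) <- c("d1", "d2", "h1", "h2")
  swapped <- structure(list(ibd_up = c("d2", "d1"), control_up = c("h2", "h1"),
                            source = list()), class = "microfam_mdsets")
  expect_equal(md_of(base), md_index(rbind(S1 = base, S2 = base), swapped,
                                     basis = "normalized")$md[1])
})

test_that("segmented truth is detected and its breakpoint recovered", {
  set.seed(31)
  n <- 500
  x <- runif(n, 0, 1.4)
  y <- 120 - 10 * x - 70 * pmax(x - 0.6, 0) + rnorm(n, 0, 4)
  fit <- fit_dysbiosis_diversity_model(data.frame(md = x, value = y),
                                       md = "md", diversity = "value")
  expect_equal(fit$selected, "segmented")
  expect_lt(abs(fit$breakpoint - 0.6), 0.05)
  expect_true(fit$breakpoint_ci[1] <= fit$breakpoint &&
                fit$breakpoint <= fit$breakpoint_ci[2])
})

test_that("linear truth keeps the linear model and penalises the quadratic", {
  set.seed(32)
  reps <- purrr::map(1:25, function(i) {
    x <- runif(120, 0, 2)
    y <- 50 - 8 * x + rnorm(120, 0, 3)
    fit <- fit_dysbiosis_diversity_model(data.frame(md = x, value = y),
                                         "md", "value")
    aics <- setNames(fit$fits$aic, fit$fits$model)
    list(sel = fit$selected, gap = aics[["quadratic"]] - aics[["linear"]])
  })
  expect_gte(mean(vapply(reps, `[[`, "", "sel") == "linear"), 0.8)
  # nesting + penalty: on linear truth the quadratic AIC exceeds the
  # linear AIC on average (2 * ll gain ~ chi2(1), penalty = 2)
  expect_gt(mean(vapply(reps, `[[`, 0, "gap")), 0)
  expect_error(fit_dysbiosis_diversity_model(
    data.frame(md = rep(1, 50), value = rnorm(50)), "md", "value"), "constant")
})

test_that("taxon sets transfer across independently simulated cohorts", {
  mk <- function(seed) simulate_cohort(simulation_config(
    n_families = 40, n_taxa = 30, seed = seed,
    disease_log2fc = c(rep(2, 3), rep(0, 24), rep(-2, 3))))
  co_a <- mk(41); co_b <- mk(42)
  res <- run_diffabund(co_a$counts, co_a$metadata,
                       contrasts = c("CD_vs_Control", "UC_vs_Control"))
  sets <- derive_md_taxa(res)
  md_b <- suppressWarnings(md_index(co_b$counts, sets))
  d <- dplyr::inner_join(md_b, co_b$metadata[c("sample_id", "diagnosis")],
                         by = "sample_id")
  expect_gt(mean(d$md[d$diagnosis != "Control"], na.rm = TRUE),
            mean(d$md[d$diagnosis == "Control"], na.rm = TRUE))
})
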