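test_that("rank-sum tests against control behave at the extremes", {
  dat <- withr::with_seed(1, tibble::tibble(
    treatment = rep(c("NEG", "SAME", "SHIFT"), each = 20),
    value = c(stats::rnorm(20), stats::rnorm(20), stats::rnorm(20) + 50)))
  res <- mann_whitney_vs_control(dat, "value", "treatment")
  same <- dplyr::filter(res, treatment == "SAME")
  shift <- dplyr::filter(res, treatment == "SHIFT")
  expect_gt(same$p_adjusted, 0.05)
  expect_lt(shift$p_adjusted, 0.001)
  expect_equal(shift$stars, "***")
  # literally identical values: no evidence whatsoever
  dat2 <- tibble::tibble(treatment = rep(c("NEG", "A"), each = 6),
                         value = rep(1:6, 2))
  res2 <- suppressWarnings(mann_whitney_vs_control(dat2, "value",
                                                   "treatment"))
  expect_gt(res2$p_adjusted, 0.9)
  expect_error(mann_whitney_vs_control(dat, "value", "treatment",
                                       control = "NOPE"), "absent")
})

test_that("small-sample p-values match exact enumeration", {
  for (seed in 1:10) {
    g <- withr::with_seed(seed, list(x = stats::rnorm(5),
                                     y = stats::rnorm(4)))
    dat <- tibble::tibble(treatment = rep(c("A", "NEG"), c(5, 4)),
                          value = c(g$x, g$y))
    res <- mann_whitney_vs_control(dat, "value", "treatment")
    expect_equal(res$p_value, mw_exact_p(g$x, g$y), tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment multiplies and saturates", {
  dat <- withr::with_seed(3, tibble::tibble(
    treatment = rep(c("NEG", LETTERS[1:10]), each = 10),
    value = stats::rnorm(110)))
  res <- mann_whitney_vs_control(dat, "value", "treatment")
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 10))
  # adjusted p is non-decreasing in the number of comparisons
  two <- mann_whitney_vs_control(
    dplyr::filter(dat, treatment %in% c("NEG", "A", "B")),
    "value", "treatment")
  a10 <- dplyr::filter(res, treatment == "A")$p_adjusted
  a2 <- dplyr::filter(two, treatment == "A")$p_adjusted
  expect_gte(a10, a2)
})

test_that("ANOVA against control flags only true shifts", {
  dat <- withr::with_seed(9, tibble::tibble(
    treatment = rep(c("NEG", "A", "B"), each = 15),
    value = c(stats::rnorm(15), stats::rnorm(15), stats::rnorm(15) + 5)))
  res <- anova_vs_control(dat, "value", "treatment")
  expect_lt(res$anova_p, 0.001)
  comp <- res$comparisons
  expect_lt(dplyr::filter(comp, treatment == "B")$p_adjusted, 0.001)
  expect_gt(dplyr::filter(comp, treatment == "A")$p_adjusted, 0.05)
  one <- tibble::tibble(treatment = rep("NEG", 5), value = rnorm(5))
  expect_error(anova_vs_control(one, "value", "treatment"), "group")
  flat <- tibble::tibble(treatment = rep(c("NEG", "A"), each = 3),
                         value = rep(c(1, 2), each = 3))
  expect_error(anova_vs_control(flat, "value", "treatment"),
               "zero within-group variance")
})

test_that("ANOVA type-I error is near nominal under the global null", {
  reps <- 400
  hits <- withr::with_seed(101, vapply(seq_len(reps), function(i) {
    dat <- tibble::tibble(treatment = rep(c("NEG", "A", "B"), each = 8),
                          value = stats::rnorm(24))
    anova_vs_control(dat, "value", "treatment")$anova_p < 0.05
  }, logical(1)))
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("correlation validates inputs and hits the trivial cases", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, x), 1)
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
  expect_error(pearson_correlation(c(1, 1, 1), x[1:3]), "zero variance")
  expect_error(pearson_correlation(c(1, NA, 3), x[1:3]), "non-finite")
})

test_that("knockdown fold-changes follow the delta-delta-Ct arithmetic", {
  dat <- tibble::tibble(
    target = "geneX", condition = c("NEG", "siRNA"),
    ct_target = c(20, 21), ct_reference = c(15, 15))
  out <- knockdown_fold_change(dat)
  expect_equal(out$relative_expression, 0.5)
  expect_equal(out$knockdown_pct, 50)
  same <- knockdown_fold_change(tibble::tibble(
    target = "geneX", condition = c("NEG", "siRNA"),
    ct_target = c(20, 20), ct_reference = c(15, 15)))
  expect_equal(same$relative_expression, 1.0)
  expect_equal(same$knockdown_pct, 0)
  # a ddCt of ~2.32 crosses the 80% knockdown screen-quality bar
  strong <- knockdown_fold_change(tibble::tibble(
    target = "geneX", condition = c("NEG", "siRNA"),
    ct_target = c(20, 22.33), ct_reference = c(15, 15)))
  expect_lte(strong$relative_expression, 0.2)
  expect_gte(strong$knockdown_pct, 80)
  expect_error(knockdown_fold_change(tibble::tibble(
    target = "geneX", condition = "siRNA", ct_target = 20,
    ct_reference = 15)), "no control")
})

test_that("fold-change is exactly invertible in ddCt", {
  for (d in c(-3, -1, 0.5, 2, 4)) {
    fwd <- knockdown_fold_change(tibble::tibble(
      target = "g", condition = c("NEG", "t"),
      ct_target = c(20, 20 + d), ct_reference = 15))
    back <- knockdown_fold_change(tibble::tibble(
      target = "g", condition = c("NEG", "t"),
      ct_target = c(20 + d, 20), ct_reference = 15))
    expect_equal(fwd$relative_expression * back$relative_expression, 1.0,
                 tolerance = 1e-12)
  }
})

test_that("replicate summaries use the mean-of-replicate-means convention", {
  dat <- tibble::tibble(
    treatment = rep("A", 6), replicate = rep(1:3, each = 2),
    value = c(1, 3, 4, 6, 7, 9))
  out <- replicate_summary(dat, "value")
  expect_equal(out$mean, mean(c(2, 5, 8)))
  expect_equal(out$sem, stats::sd(c(2, 5, 8)) / sqrt(3))
  expect_equal(out$n_replicates, 3)
})

test_that("significance stars follow the conventional thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", ""))
})
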