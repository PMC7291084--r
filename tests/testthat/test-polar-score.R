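test_that("fragment angles follow the atan2 axis convention", {
  c0 <- c(10, 10)
  expect_equal(fragment_angles(11, 10, c0), 0)
  expect_equal(fragment_angles(10, 11, c0), pi / 2)
  expect_equal(fragment_angles(9, 10, c0), pi)
  expect_equal(fragment_angles(10, 9, c0), -pi / 2)
  expect_warning(a <- fragment_angles(c(10, 11), c(10, 10), c0),
                 "at the centre")
  expect_length(a, 1)
})

test_that("circular mean is the resultant direction, with degeneracy flag", {
  cm <- circular_mean(c(0.1, 0.3))
  expect_equal(cm$mean, 0.2, tolerance = 1e-12)
  expect_false(cm$degenerate)
  expect_equal(circular_mean(c(pi / 4, -pi / 4))$mean, 0)
  deg <- circular_mean(c(pi / 2, -pi / 2))
  expect_true(deg$degenerate)
  expect_equal(deg$mean, 0)
  # mean across the wrap point
  expect_equal(circular_mean(c(pi - 0.1, -pi + 0.1))$mean, pi,
               tolerance = 1e-8)
})

test_that("normalizing angles yields zero circular mean within (-pi, pi]", {
  expect_equal(normalize_angles(rep(1.3, 5), 1.3), rep(0, 5))
  expect_equal(normalize_angles(c(0.1, 0.3), 0.2), c(-0.1, 0.1))
  w <- normalize_angles(-pi + 0.1, -pi)
  expect_equal(w, 0.1)
  for (seed in 1:20) {
    a <- withr::with_seed(seed, stats::runif(15, -pi, pi))
    cm <- circular_mean(a)
    norm <- normalize_angles(a, cm$mean)
    expect_true(all(norm > -pi & norm <= pi))
    expect_lt(abs(circular_mean(norm)$mean), 1e-8)
  }
})

test_that("polar histogram bins half-open sectors with upper-edge assignment", {
  centers <- -pi + (0:7 + 0.5) * pi / 4
  h <- polar_histogram(centers, n_bins = 8)
  expect_equal(h$frequencies, rep(0.125, 8))
  h1 <- polar_histogram(0.3)
  expect_equal(sum(h1$frequencies), 1)
  expect_equal(sort(h1$frequencies, decreasing = TRUE)[1], 1)
  # an interior edge angle goes to the bin above it
  edge <- -pi + 3 * pi / 4
  he <- polar_histogram(edge)
  expect_equal(he$counts[4], 1)
})

test_that("the score matches its closed-form extremes and a brute-force sum", {
  expect_equal(polar_distribution_score(c(1, rep(0, 7))), 1.75)
  expect_equal(polar_distribution_score(rep(0.125, 8)), 0)
  expect_equal(polar_distribution_score(c(0.5, 0.5, rep(0, 6))), 1.5)
  expect_error(polar_distribution_score(rep(0, 8)), "undefined")
  h0 <- structure(list(counts = rep(0, 8), frequencies = rep(NaN, 8),
                       n_bins = 8L), class = "polar_histogram")
  expect_error(polar_distribution_score(h0), "undefined")
})

test_that("a single-fragment cell scores the maximum", {
  res <- pds_for_cell(tibble::tibble(x_px = 12, y_px = 40), c(10, 10))
  expect_equal(res$pds, 1.75)
  expect_equal(res$n_fragments, 1)
})

test_that("symmetric bin-center fragments are degenerate and score zero", {
  centers <- -pi + (0:7 + 0.5) * pi / 4
  frag <- tibble::tibble(x_px = 10 + cos(centers), y_px = 10 + sin(centers))
  res <- pds_for_cell(frag, c(10, 10))
  expect_true(res$degenerate)
  expect_equal(res$pds, 0)
})

test_that("vectorized score equals the brute-force oracle on random cells", {
  for (seed in 1:300) {
    dat <- withr::with_seed(seed, {
      n <- sample(1:40, 1)
      list(x = stats::runif(n, -5, 5), y = stats::runif(n, -5, 5))
    })
    res <- pds_for_cell(tibble::tibble(x_px = dat$x, y_px = dat$y), c(0, 0))
    expect_equal(res$pds, pds_bruteforce(dat$x, dat$y, 0, 0),
                 tolerance = 1e-12)
  }
})

test_that("the score is invariant to rotation and radial rescaling", {
  for (seed in 1:100) {
    trial <- withr::with_seed(seed, {
      n <- sample(3:30, 1)
      list(x = stats::rnorm(n), y = stats::rnorm(n),
           rot = stats::runif(1, -pi, pi), scl = stats::runif(1, 0.2, 5))
    })
    base <- pds_for_cell(tibble::tibble(x_px = trial$x, y_px = trial$y),
                         c(0, 0))$pds
    xr <- trial$x * cos(trial$rot) - trial$y * sin(trial$rot)
    yr <- trial$x * sin(trial$rot) + trial$y * cos(trial$rot)
    expect_equal(pds_for_cell(tibble::tibble(x_px = xr, y_px = yr),
                              c(0, 0))$pds, base, tolerance = 1e-12)
    expect_equal(pds_for_cell(tibble::tibble(x_px = trial$x * trial$scl,
                                             y_px = trial$y * trial$scl),
                              c(0, 0))$pds, base, tolerance = 1e-12)
  }
})

test_that("the score stays within its analytic bounds", {
  for (seed in 1:500) {
    dat <- withr::with_seed(seed + 1000, {
      n <- sample(1:60, 1)
      list(x = stats::rnorm(n), y = stats::rnorm(n))
    })
    p <- pds_for_cell(tibble::tibble(x_px = dat$x, y_px = dat$y), c(0, 0))$pds
    expect_gte(p, 0)
    expect_lte(p, 1.75)
  }
})

test_that("per-cell scoring skips empty cells and joins treatments", {
  cells <- tibble::tibble(cell_id = 1:3, x_px = c(0, 100, 200),
                          y_px = c(0, 0, 0),
                          treatment = c("NEG", "NEG", "KD"))
  frag <- tibble::tibble(
    cell_id = c(1, 1, 1, 2, 2),
    x_px = c(3, 4, 5, 103, 98),
    y_px = c(0, 1, -1, 2, -3))
  expect_message(res <- pds_by_cell(frag, cells), "zero fragments")
  expect_equal(nrow(res), 2)
  expect_true(all(c("pds", "treatment") %in% names(res)))
  expect_error(pds_for_cell(frag[0, ], c(0, 0)), "no fragments")
})

test_that("treatment normalization divides by the control mean", {
  scores <- tibble::tibble(
    treatment = rep(c("NEG", "A", "B"), each = 4),
    pds = c(rep(0.7, 4), rep(0.35, 4), rep(0.7, 4)))
  out <- normalize_pds(scores)
  expect_equal(out$normalized_pds[out$treatment == "A"], 0.5)
  expect_equal(out$normalized_pds[out$treatment == "B"], 1.0)
  expect_equal(out$normalized_pds[out$treatment == "NEG"], 1.0)
  zero <- tibble::tibble(treatment = rep(c("NEG", "A"), each = 2),
                         pds = c(0, 0, 1, 1))
  expect_error(normalize_pds(zero), "cannot normalize")
  expect_error(normalize_pds(scores, control = "MISSING"), "absent")
})
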