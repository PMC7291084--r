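test_that("scene generation is deterministic and validates inputs", {
  a <- generate_cell_scene(2, golgi_spec(n_fragments = 6), seed = 11)
  b <- generate_cell_scene(2, golgi_spec(n_fragments = 6), seed = 11)
  expect_identical(a, b)
  c <- generate_cell_scene(2, golgi_spec(n_fragments = 6), seed = 12)
  expect_false(identical(a$fragments, c$fragments))
  expect_error(generate_cell_scene(0), "n_cells")
  expect_error(generate_cell_scene(4, image_size = c(100, 100)),
               "image too small|non-overlapping")
  expect_error(generate_cell_scene(1, golgi_spec(radial_range = c(1, 20))),
               "radial_range")
})

test_that("high angular concentration collapses fragments into one sector", {
  sc <- generate_cell_scene(1, golgi_spec(n_fragments = 10, kappa = 1e6),
                            seed = 7, render = FALSE)
  ref <- sc$cells$ref_angle[1]
  dev <- atan2(sin(sc$fragments$angle_truth - ref),
               cos(sc$fragments$angle_truth - ref))
  expect_lt(max(dev) - min(dev), pi / 4)
})

test_that("zero concentration gives a uniform angular distribution", {
  sc <- generate_cell_scene(1, golgi_spec(n_fragments = 8000, kappa = 0,
                                          radial_range = c(1.5, 4)),
                            seed = 7, render = FALSE)
  h <- polar_histogram(sc$fragments$angle_truth, n_bins = 8)
  expect_true(all(abs(h$frequencies - 0.125) <= 0.02))
  # direct multinomial oracle at the same n: the spread of a fair 8-sided
  # multinomial at n = 8000 comfortably brackets the observed deviations
  osc <- withr::with_seed(7, table(factor(sample(1:8, 8000, TRUE), 1:8)))
  expect_true(all(abs(as.numeric(osc) / 8000 - 0.125) <= 0.02))
})

test_that("truth fragments lie inside their parent cell masks", {
  sc <- generate_cell_scene(4, golgi_spec(n_fragments = 15, kappa = 2),
                            puncta_count = 10, seed = 3, render = FALSE)
  for (i in seq_len(nrow(sc$fragments))) {
    f <- sc$fragments[i, ]
    expect_equal(sc$cell_labels[round(f$x_px), round(f$y_px)], f$cell_id)
  }
  for (i in seq_len(nrow(sc$puncta))) {
    p <- sc$puncta[i, ]
    expect_equal(sc$cell_labels[round(p$x_px), round(p$y_px)], p$cell_id)
  }
  # every nucleus centroid inside its cell
  for (i in seq_len(nrow(sc$cells))) {
    expect_equal(sc$cell_labels[round(sc$cells$nuc_x_px[i]),
                                round(sc$cells$nuc_y_px[i])],
                 sc$cells$cell_id[i])
  }
})

test_that("rendering conserves counts and integrated intensity", {
  cal <- image_calibration()
  objs <- tibble::tibble(x_px = c(30, 70, 50), y_px = c(30, 30, 75),
                         radius_px = c(4, 3, 5), intensity = c(10, 20, 5),
                         type = "disc")
  sharp <- render_channel(objs, c(100, 100), psf_sigma = 0, background = 100)
  expect_equal(max(table(sharp)), sum(sharp == 100))
  lab <- EBImage::bwlabel(EBImage::Image((sharp > 100) * 1))
  expect_equal(max(lab), 3)
  blurred <- render_channel(objs, c(100, 100), psf_sigma = 1,
                            background = 100)
  expect_equal(sum(blurred - 100), sum(sharp - 100), tolerance = 0.01)
  flat <- render_channel(NULL, c(20, 20), background = 100)
  expect_true(all(flat == 100))
})

test_that("straight-path truth tracks move exactly speed * interval", {
  cal <- image_calibration(pixel_size = 0.1, frame_interval = 1)
  tl <- generate_timelapse(carrier_spec(1, speed = 1, path = "straight"),
                           n_frames = 10, calibration = cal, seed = 5,
                           render = FALSE)
  steps <- sqrt(diff(tl$tracks$x_um)^2 + diff(tl$tracks$y_um)^2)
  expect_equal(steps, rep(1.0, length(steps)), tolerance = 1e-12)
  still <- generate_timelapse(carrier_spec(1, speed = 0), n_frames = 5,
                              seed = 5, render = FALSE)
  expect_equal(length(unique(still$tracks$x_um)), 1)
  expect_equal(length(unique(still$tracks$y_um)), 1)
  expect_error(generate_timelapse(carrier_spec(1), n_frames = 1), "n_frames")
})

test_that("a carrier leaving the field is truncated and flagged", {
  cal <- image_calibration()
  start <- matrix(c(1, 25.6), 1, 2) # 1 um from the left edge
  tl <- generate_timelapse(
    carrier_spec(1, speed = 2, start_positions = start),
    n_frames = 60, calibration = cal, seed = 42, render = FALSE)
  expect_true(all(tl$tracks$left_fov))
  expect_lt(max(tl$tracks$frame), 60)
  expect_true(all(tl$tracks$x_um >= 0 & tl$tracks$x_um <= 51.2))
})

test_that("rendered tubules measure close to their nominal length", {
  cal <- image_calibration()
  tl <- generate_timelapse(
    carrier_spec(1, speed = 0.3, length = 2.5,
                 start_positions = matrix(c(25, 25), 1, 2)),
    n_frames = 2, calibration = cal, seed = 9, image_size = c(512, 512))
  fr <- tl$channels$carrier[, , 1]
  len_um <- rod_length_moment(fr, background = 20, sigma_px = 1.5) *
    cal$pixel_size
  expect_equal(len_um, 2.5, tolerance = 0.1)
})

test_that("mean truth-angle PDS is non-decreasing in angular concentration", {
  kappas <- c(0, 1, 4, 16, 1e6)
  means <- vapply(seq_along(kappas), function(i) {
    sc <- generate_cell_scene(60, golgi_spec(n_fragments = 12,
                                             kappa = kappas[i]),
                              seed = 100 + i, render = FALSE)
    mean(pds_by_cell(sc$fragments, sc$cells)$pds)
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-9))
})
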