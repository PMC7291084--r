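test_that("preprocessing subtracts, clips, blurs and multiplies in order", {
  fr <- matrix(10, 20, 20)
  expect_true(all(preprocess_stack(fr) == 0))
  fr2 <- matrix(25, 20, 20)
  out <- preprocess_stack(fr2)
  expect_equal(out[10, 10], 3 * (25 - 10))
  fr3 <- matrix(5, 20, 20)
  expect_true(all(preprocess_stack(fr3) == 0))
  stack <- array(25, dim = c(10, 10, 3))
  ps <- preprocess_stack(stack)
  expect_equal(dim(ps), dim(stack))
  expect_equal(ps[5, 5, 2], 45)
})

test_that("track statistics give textbook speeds and displacements", {
  cal <- image_calibration(pixel_size = 1, frame_interval = 1) # 1 um/px
  trk <- tibble::tibble(track_id = 1, frame = 1:3,
                        x_px = c(0, 1, 2), y_px = c(0, 0, 0))
  st <- track_statistics(trk, cal)
  expect_equal(st$mean_speed_um_s, 1)
  expect_equal(st$displacement_um, 2)
  trk2 <- tibble::tibble(track_id = 1, frame = 1:2,
                         x_px = c(0, 3), y_px = c(0, 4))
  expect_equal(track_statistics(trk2, cal)$mean_speed_um_s, 5)
  still <- tibble::tibble(track_id = 1, frame = 1:4, x_px = 2, y_px = 2)
  st3 <- track_statistics(still, cal)
  expect_equal(st3$mean_speed_um_s, 0)
  expect_equal(st3$displacement_um, 0)
  # displacement can never exceed path length
  wig <- tibble::tibble(track_id = 1, frame = 1:5,
                        x_px = c(0, 1, 0, 2, 1), y_px = c(0, 1, 2, 2, 0))
  stw <- track_statistics(wig, cal)
  expect_lte(stw$displacement_um, stw$path_length_um)
})

test_that("track filtering is strict at the cutoff and idempotent", {
  st <- tibble::tibble(track_id = 1:3,
                       displacement_um = c(2.0, 2.01, 5),
                       mean_speed_um_s = 1)
  kept <- filter_tracks(st)
  expect_equal(kept$track_id, c(2, 3))
  expect_identical(filter_tracks(kept), kept)
  expect_equal(nrow(filter_tracks(st[0, ])), 0)
})

test_that("the tubular boundary sits exactly at 2 um, inclusive", {
  lengths <- seq(0, 4, by = 0.01)
  cls <- classify_carrier(lengths)
  expect_true(all(cls$class[lengths < 2] == "vesicular"))
  expect_true(all(cls$class[lengths >= 2] == "tubular"))
  transition <- lengths[min(which(cls$class == "tubular"))]
  expect_equal(transition, 2.00)
  expect_equal(as.character(classify_carrier(3.5)$size_bin), ">=3 um")
  expect_equal(as.character(classify_carrier(2.0)$class), "tubular")
  expect_equal(as.character(classify_carrier(1.99)$class), "vesicular")
  expect_error(classify_carrier(-1), ">= 0")
})

test_that("detection measures tubule length and flags point carriers small", {
  cal <- image_calibration()
  tl <- generate_timelapse(
    carrier_spec(1, speed = 0.3, length = 2.5,
                 start_positions = matrix(c(25, 25), 1, 2)),
    n_frames = 2, calibration = cal, seed = 9)
  fr <- preprocess_stack(tl$channels$carrier[, , 1])
  det <- detect_carriers(fr, cal)
  expect_equal(nrow(det), 1)
  expect_equal(det$length_um, 2.5, tolerance = 0.1)
  pt <- generate_timelapse(
    carrier_spec(1, speed = 0.3, start_positions = matrix(c(25, 25), 1, 2)),
    n_frames = 2, calibration = cal, seed = 9)
  detp <- detect_carriers(preprocess_stack(pt$channels$carrier[, , 1]), cal)
  expect_lt(detp$length_um, 2)
  blank <- detect_carriers(matrix(0, 64, 64), cal)
  expect_equal(nrow(blank), 0)
})

test_that("two well-separated carriers stay on distinct tracks", {
  cal <- image_calibration()
  starts <- matrix(c(10, 10, 40, 40), 2, 2, byrow = TRUE)
  tl <- generate_timelapse(
    carrier_spec(2, speed = 0.5, start_positions = starts),
    n_frames = 20, calibration = cal, seed = 13)
  arr <- preprocess_stack(tl$channels$carrier)
  dets <- dplyr::bind_rows(lapply(seq_len(dim(arr)[3]), function(f) {
    d <- detect_carriers(arr[, , f], cal)
    d$frame <- f
    d
  }))
  linked <- link_tracks(dets, cal)
  expect_equal(dplyr::n_distinct(linked$track_id), 2)
  # each linked track matches one truth carrier frame-for-frame
  for (tid in unique(linked$track_id)) {
    trk <- dplyr::arrange(dplyr::filter(linked, track_id == tid), frame)
    truth_id <- which.min(abs(tl$tracks$x_px[tl$tracks$frame == 1] -
                                trk$x_px[1]))
    truth <- dplyr::filter(tl$tracks, carrier_id == truth_id)
    m <- min(nrow(trk), nrow(truth))
    expect_lt(max(abs(trk$x_px[1:m] - truth$x_px[1:m])), 1)
    expect_lt(max(abs(trk$y_px[1:m] - truth$y_px[1:m])), 1)
  }
  expect_error(link_tracks(dets[dets$frame == 1, ], cal), "2 frames")
})

test_that("straight-run speeds are recovered within five percent", {
  cal <- image_calibration()
  for (v in c(0.2, 1.0)) {
    tl <- generate_timelapse(
      carrier_spec(1, speed = v, start_positions = matrix(c(25.6, 25.6),
                                                          1, 2)),
      n_frames = 30, calibration = cal, seed = 77)
    res <- track_carrier_screen(list(NEG = tl), min_displacement = 0)
    expect_equal(res$per_treatment$mean_speed_um_s, v, tolerance = 0.05)
  }
})

test_that("tubular-cell prevalence is computed per cell", {
  tab <- tibble::tibble(cell_id = rep(1:4, each = 2),
                        length_um = c(2.5, 0.5, 1, 1, 3, 0.2, 0.1, NA))
  expect_equal(percent_cells_with_tubular(tab), 50)
  all_tub <- tibble::tibble(cell_id = 1:5, length_um = 2.5)
  expect_equal(percent_cells_with_tubular(all_tub), 100)
  none <- tibble::tibble(cell_id = 1:5, length_um = 0.5)
  expect_equal(percent_cells_with_tubular(none), 0)
  expect_error(percent_cells_with_tubular(none[0, ]), "no cells")
  # programmed prevalence is recovered within binomial error at n = 100
  prev <- withr::with_seed(55, stats::rbinom(100, 1, 0.55))
  cells <- tibble::tibble(cell_id = 1:100,
                          length_um = ifelse(prev == 1, 2.5, 0.8))
  est <- percent_cells_with_tubular(cells)
  expect_lt(abs(est - 55), 1.96 * sqrt(0.55 * 0.45 / 100) * 100)
})
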