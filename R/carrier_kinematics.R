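#' Preprocess a time-lapse stack for carrier detection
#'
#' The standard carrier-video recipe: subtract a constant (clipping at zero,
#' as an unsigned-image pipeline does), Gaussian-blur each frame, then
#' multiply, frame by frame.
#'
#' @param stack 3D numeric array (x, y, frame) or a single 2D frame.
#' @param subtract_constant Intensity offset removed first (default 10).
#' @param gaussian_sigma Blur sigma in pixels (default 1; 0 skips the blur).
#' @param multiply_factor Gain applied last (default 3).
#' @return Array of the same shape.
#' @export
preprocess_stack <- function(stack, subtract_constant = 10,
                             gaussian_sigma = 1, multiply_factor = 3) {
  stopifnot(gaussian_sigma >= 0, multiply_factor > 0)
  one <- function(fr) {
    fr <- pmax(fr - subtract_constant, 0)
    if (gaussian_sigma > 0 && any(fr > 0))
      fr <- as.matrix(EBImage::imageData(EBImage::gblur(
        EBImage::Image(fr), sigma = gaussian_sigma)))
    fr * multiply_factor
  }
  if (length(dim(stack)) == 2) return(one(stack))
  stopifnot(length(dim(stack)) == 3)
  out <- stack
  for (f in seq_len(dim(stack)[3])) out[, , f] <- one(stack[, , f])
  out
}

# Pixel length of a labelled object: for elongated shapes, extent along the
# principal axis minus the width (a stadium-shape correction approximating the
# skeleton length); for compact shapes, the equivalent-circle diameter.
object_length_px <- function(px_coords) {
  n <- nrow(px_coords)
  eq_diam <- 2 * sqrt(n / pi)
  if (n < 3) return(eq_diam)
  cen <- colMeans(px_coords)
  cc <- sweep(px_coords, 2, cen)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  proj_major <- cc %*% ev$vectors[, 1]
  proj_minor <- cc %*% ev$vectors[, 2]
  major <- diff(range(proj_major)) + 1
  minor <- diff(range(proj_minor)) + 1
  if (major >= 2 * minor) major - minor else eq_diam
}

#' Detect carriers in one (preprocessed) frame
#'
#' Thresholds the frame, labels 4-connected components, and measures each
#' object's intensity-weighted centroid, area, and physical length. Length is
#' the principal-axis extent (width-corrected) for elongated objects and the
#' equivalent-circle diameter for compact ones, in micrometres.
#'
#' @param frame 2D numeric matrix (already preprocessed).
#' @param calibration An [image_calibration()].
#' @param threshold `"otsu"` or a numeric cutoff; for clean synthetic frames
#'   any value above background works.
#' @param min_area_px Minimum object area kept.
#' @return A tibble (possibly empty): `x_px`, `y_px`, `area_px`,
#'   `length_um`.
#' @export
detect_carriers <- function(frame, calibration = image_calibration(),
                            threshold = "otsu", min_area_px = 4) {
  stopifnot(is.matrix(frame))
  empty <- tibble::tibble(x_px = numeric(), y_px = numeric(),
                          area_px = numeric(), length_um = numeric())
  rng <- range(frame)
  if (rng[1] == rng[2]) return(empty)
  thr <- if (identical(threshold, "otsu")) {
    scaled <- (frame - rng[1]) / (rng[2] - rng[1])
    rng[1] + EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1])
  } else threshold
  mask <- frame > thr
  if (!any(mask)) return(empty)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(
    EBImage::Image(mask * 1))))
  storage.mode(lab) <- "integer"
  lab <- filter_small_labels(lab, min_area_px)
  if (max(lab) == 0) return(empty)
  rows <- lapply(seq_len(max(lab)), function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    w <- frame[px]
    tibble::tibble(
      x_px = sum(px[, 1] * w) / sum(w),
      y_px = sum(px[, 2] * w) / sum(w),
      area_px = nrow(px),
      length_um = px_to_um(object_length_px(px), calibration))
  })
  dplyr::bind_rows(rows)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames: each track
#' is extended by its closest detection in the next frame provided the step is
#' at most `max_step` micrometres; unmatched detections start new tracks. No
#' gap closing.
#'
#' @param detections Tibble of detections with columns `frame`, `x_px`,
#'   `y_px` (and any per-detection extras, carried along).
#' @param calibration An [image_calibration()].
#' @param max_step Maximum link distance per frame pair, micrometres.
#' @return The detections tibble with a `track_id` column, ordered by track
#'   and frame.
#' @export
link_tracks <- function(detections, calibration = image_calibration(),
                        max_step = 1.5) {
  stopifnot("frame" %in% names(detections))
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2)
    stop("need detections from at least 2 frames to link", call. = FALSE)
  max_step_px <- um_to_px(max_step, calibration)
  det <- dplyr::arrange(detections, .data$frame)
  det$track_id <- NA_integer_
  next_id <- 0L
  prev_idx <- which(det$frame == frames[1])
  det$track_id[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx)
  for (fi in seq_along(frames)[-1]) {
    cur_idx <- which(det$frame == frames[fi])
    if (length(prev_idx) > 0 && length(cur_idx) > 0) {
      d <- outer(seq_along(prev_idx), seq_along(cur_idx),
                 Vectorize(function(i, j)
                   sqrt((det$x_px[prev_idx[i]] - det$x_px[cur_idx[j]])^2 +
                        (det$y_px[prev_idx[i]] - det$y_px[cur_idx[j]])^2)))
      d <- matrix(d, length(prev_idx), length(cur_idx))
      # greedy: repeatedly take the globally closest remaining pair
      repeat {
        m <- which.min(d)
        if (length(m) == 0 || d[m] > max_step_px || !is.finite(d[m])) break
        i <- (m - 1) %% nrow(d) + 1; j <- (m - 1) %/% nrow(d) + 1
        det$track_id[cur_idx[j]] <- det$track_id[prev_idx[i]]
        d[i, ] <- Inf; d[, j] <- Inf
        if (all(!is.finite(d))) break
      }
    }
    new <- cur_idx[is.na(det$track_id[cur_idx])]
    if (length(new)) {
      det$track_id[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  dplyr::arrange(det, .data$track_id, .data$frame)
}

#' Per-track speed and displacement
#'
#' Mean speed is the summed consecutive step distance divided by the track
#' duration; displacement length is the straight-line start-to-end distance.
#' Tracks with fewer than two detections are dropped.
#'
#' @param tracks Tibble with `track_id`, `frame`, `x_px`, `y_px` (and
#'   optionally `length_um` per detection, summarised as its per-track mean
#'   and maximum).
#' @param calibration An [image_calibration()].
#' @return A tibble per track: `track_id`, `n_detections`, `duration_s`,
#'   `path_length_um`, `displacement_um`, `mean_speed_um_s` (plus
#'   `mean_length_um`/`max_length_um` when available).
#' @export
track_statistics <- function(tracks, calibration = image_calibration()) {
  stopifnot(all(c("track_id", "frame", "x_px", "y_px") %in% names(tracks)))
  one <- function(df) {
    df <- dplyr::arrange(df, .data$frame)
    if (nrow(df) < 2) return(NULL)
    dur <- (max(df$frame) - min(df$frame)) * calibration$frame_interval
    if (dur <= 0) stop("track duration is zero", call. = FALSE)
    steps <- sqrt(diff(df$x_px)^2 + diff(df$y_px)^2)
    path_um <- px_to_um(sum(steps), calibration)
    disp_um <- px_to_um(sqrt((df$x_px[nrow(df)] - df$x_px[1])^2 +
                             (df$y_px[nrow(df)] - df$y_px[1])^2), calibration)
    out <- tibble::tibble(n_detections = nrow(df), duration_s = dur,
                          path_length_um = path_um,
                          displacement_um = disp_um,
                          mean_speed_um_s = path_um / dur)
    if ("length_um" %in% names(df)) {
      out$mean_length_um <- mean(df$length_um)
      out$max_length_um <- max(df$length_um)
    }
    out
  }
  res <- dplyr::group_modify(dplyr::group_by(tracks, .data$track_id),
                             function(df, key) one(df) %||% tibble::tibble())
  dplyr::ungroup(res)
}

#' Filter tracks by displacement length
#'
#' Keeps tracks whose straight-line displacement strictly exceeds
#' `min_displacement` micrometres (the conventional cutoff of 2 µm removes
#' jittering, effectively stationary objects). Idempotent.
#'
#' @param track_stats Per-track tibble from [track_statistics()].
#' @param min_displacement Cutoff in micrometres (strict `>`; default 2).
#' @return The filtered tibble.
#' @export
filter_tracks <- function(track_stats, min_displacement = 2) {
  stopifnot("displacement_um" %in% names(track_stats))
  dplyr::filter(track_stats, .data$displacement_um > min_displacement)
}

#' Classify a carrier as tubular or vesicular by length
#'
#' A carrier is tubular when its length is 2 µm or more, vesicular when it is
#' shorter. For tubular-fraction reporting, lengths are also binned as
#' `[1,2)`, `[2,3)` and `>=3` µm.
#'
#' @param length_um Numeric vector of carrier lengths in micrometres (>= 0).
#' @param tubular_min Length at and above which a carrier is tubular
#'   (inclusive; default 2 µm).
#' @return A tibble: `length_um`, `class` (factor `vesicular`/`tubular`),
#'   `size_bin` (factor `<1 um`, `1-2 um`, `2-3 um`, `>=3 um`).
#' @export
classify_carrier <- function(length_um, tubular_min = 2) {
  if (any(length_um < 0)) stop("carrier length must be >= 0", call. = FALSE)
  cls <- factor(ifelse(length_um >= tubular_min, "tubular", "vesicular"),
                levels = c("vesicular", "tubular"))
  bin <- cut(length_um, breaks = c(-Inf, 1, 2, 3, Inf), right = FALSE,
             labels = c("<1 um", "1-2 um", "2-3 um", ">=3 um"))
  tibble::tibble(length_um = length_um, class = cls, size_bin = bin)
}

#' Percentage of cells containing at least one tubular carrier
#'
#' @param cell_carriers Tibble with one row per carrier, columns `cell_id`
#'   and `length_um` (cells with no carriers must still appear, with
#'   `length_um = NA`).
#' @param tubular_min Tubular cutoff in micrometres (default 2).
#' @return Percentage in `[0, 100]`.
#' @export
percent_cells_with_tubular <- function(cell_carriers, tubular_min = 2) {
  stopifnot(all(c("cell_id", "length_um") %in% names(cell_carriers)))
  if (nrow(cell_carriers) == 0) stop("no cells provided", call. = FALSE)
  per_cell <- dplyr::summarise(
    dplyr::group_by(cell_carriers, .data$cell_id),
    has_tubular = any(!is.na(.data$length_um) &
                        .data$length_um >= tubular_min),
    .groups = "drop")
  100 * mean(per_cell$has_tubular)
}
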