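#' Golgi dispersion specification
#'
#' Describes how organelle fragments are placed around each synthetic cell's
#' centre: how many fragments, how tightly their angular positions concentrate
#' about the cell's juxtanuclear reference direction, and how far from the
#' centre and how large they are. Angles are drawn from a wrapped-normal
#' distribution with standard deviation `1/sqrt(kappa)`, so `kappa = 0` gives a
#' uniform ring of fragments (fully dispersed) and large `kappa` collapses all
#' fragments onto the reference direction (fully juxtanuclear).
#'
#' @param n_fragments Number of fragments per cell (count >= 0).
#' @param kappa Angular concentration (>= 0). 0 = uniform; `Inf`-like values
#'   (e.g. 1e6) = a single tight sector.
#' @param radial_range Length-2 numeric, min/max distance of fragment centres
#'   from the cell centre, in micrometres.
#' @param fragment_radius_range Length-2 numeric, min/max fragment disc radius
#'   in micrometres (both > 0).
#' @param intensity_mean Mean fluorescence amplitude of a fragment (arbitrary
#'   units).
#' @param min_separation Minimum pairwise distance between fragment centres
#'   in micrometres (default 0 = unconstrained). Setting this above the
#'   fragment diameter plus the PSF width guarantees optically resolvable
#'   fragments, at the cost of restricting feasible `n_fragments`/`kappa`
#'   combinations.
#' @return An object of class `golgi_spec`.
#' @export
golgi_spec <- function(n_fragments = 12, kappa = 8,
                       radial_range = c(1.5, 4.5),
                       fragment_radius_range = c(0.15, 0.35),
                       intensity_mean = 200, min_separation = 0) {
  stopifnot(n_fragments >= 0, kappa >= 0,
            length(radial_range) == 2, all(radial_range >= 0),
            radial_range[1] <= radial_range[2],
            length(fragment_radius_range) == 2,
            all(fragment_radius_range > 0),
            fragment_radius_range[1] <= fragment_radius_range[2],
            intensity_mean > 0, min_separation >= 0)
  structure(list(n_fragments = as.integer(n_fragments), kappa = kappa,
                 radial_range = radial_range,
                 fragment_radius_range = fragment_radius_range,
                 intensity_mean = intensity_mean,
                 min_separation = min_separation),
            class = "golgi_spec")
}

#' Carrier specification for time-lapse simulation
#'
#' Describes a population of moving membrane carriers: point-like vesicles
#' (`length = 0`) or tubules (`length > 0`, rendered as line segments), moving
#' along straight paths or random walks at a fixed speed.
#'
#' @param n_carriers Number of carriers (count >= 1).
#' @param speed Speed in micrometres per second (>= 0).
#' @param path `"straight"` (fixed random heading per carrier) or
#'   `"random-walk"` (a new random heading every frame).
#' @param length Carrier length in micrometres; 0 renders a point-like spot.
#' @param start_positions Optional n x 2 matrix of starting positions in
#'   micrometres; `NULL` places carriers uniformly at random inside the field.
#' @param intensity Peak fluorescence amplitude (arbitrary units).
#' @return An object of class `carrier_spec`.
#' @export
carrier_spec <- function(n_carriers = 1, speed = 0.5,
                         path = c("straight", "random-walk"),
                         length = 0, start_positions = NULL,
                         intensity = 200) {
  path <- match.arg(path)
  stopifnot(n_carriers >= 1, speed >= 0, length >= 0, intensity > 0)
  if (!is.null(start_positions)) {
    start_positions <- as.matrix(start_positions)
    stopifnot(ncol(start_positions) == 2, nrow(start_positions) == n_carriers)
  }
  structure(list(n_carriers = as.integer(n_carriers), speed = speed,
                 path = path, length = length,
                 start_positions = start_positions, intensity = intensity),
            class = "carrier_spec")
}

# Wrapped-normal angular draws about `mu` with concentration kappa.
# kappa = 0 is the uniform circular distribution; sd = 1/sqrt(kappa) otherwise.
rwrapped <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  wrap_angle(mu + stats::rnorm(n, 0, 1 / sqrt(kappa)))
}

# Rasterize a star-convex boundary (radius as a function of polar angle)
# within its bounding box only; returns row/col indices and an inside mask so
# callers can paste into a full-size label map cheaply.
rasterize_boundary <- function(dim, cx, cy, radius_fun, rmax) {
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(dim[1], ceiling(cx + rmax))
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(dim[2], ceiling(cy + rmax))
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  dx <- X - cx; dy <- Y - cy
  th <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  list(xs = xs, ys = ys, inside = r <= radius_fun(th))
}

add_disc <- function(img, cx, cy, radius, value) {
  x0 <- max(1L, floor(cx - radius - 1)); x1 <- min(nrow(img), ceiling(cx + radius + 1))
  y0 <- max(1L, floor(cy - radius - 1)); y1 <- min(ncol(img), ceiling(cy + radius + 1))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, length(xs), length(ys))
  dy <- matrix(ys - cy, length(xs), length(ys), byrow = TRUE)
  inside <- (dx^2 + dy^2) <= radius^2
  img[xs, ys] <- img[xs, ys] + value * inside
  img
}

add_segment <- function(img, cx, cy, angle, length, thickness, value) {
  hx <- cos(angle) * length / 2; hy <- sin(angle) * length / 2
  p1 <- c(cx - hx, cy - hy); p2 <- c(cx + hx, cy + hy)
  pad <- thickness / 2 + 1
  x0 <- max(1L, floor(min(p1[1], p2[1]) - pad))
  x1 <- min(nrow(img), ceiling(max(p1[1], p2[1]) + pad))
  y0 <- max(1L, floor(min(p1[2], p2[2]) - pad))
  y1 <- min(ncol(img), ceiling(max(p1[2], p2[2]) + pad))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(add_disc(img, cx, cy, thickness / 2, value))
  t <- pmin(1, pmax(0, ((X - p1[1]) * vx + (Y - p1[2]) * vy) / len2))
  dx <- X - (p1[1] + t * vx); dy <- Y - (p1[2] + t * vy)
  inside <- (dx^2 + dy^2) <= (thickness / 2)^2
  img[xs, ys] <- img[xs, ys] + value * inside
  img
}

#' Render a fluorescence channel from ground-truth objects
#'
#' Renders solid discs and line segments onto a constant background, then
#' applies a Gaussian point-spread blur. Blur conserves integrated intensity
#' away from the image borders, so the total above-background signal is
#' proportional to the summed object areas times intensities regardless of
#' `psf_sigma`.
#'
#' @param objects A data frame with columns `x_px`, `y_px`, `intensity`, and
#'   either `radius_px` (discs) or `length_px` + `angle` + `thickness_px`
#'   (segments); a `type` column (`"disc"`/`"segment"`) selects per row. An
#'   empty or `NULL` data frame renders pure background.
#' @param dim Length-2 integer image dimensions (x, y) in pixels.
#' @param psf_sigma Gaussian PSF standard deviation in micrometres (>= 0).
#' @param background Constant background intensity.
#' @param calibration An [image_calibration()].
#' @return A numeric matrix of dimensions `dim`.
#' @export
render_channel <- function(objects, dim, psf_sigma = 0.15, background = 0,
                           calibration = image_calibration()) {
  stopifnot(psf_sigma >= 0, length(dim) == 2)
  img <- matrix(0, dim[1], dim[2])
  if (!is.null(objects) && nrow(objects) > 0) {
    type <- if ("type" %in% names(objects)) objects$type else
      ifelse(!is.null(objects$radius_px) & !is.na(objects$radius_px %||% NA),
             "disc", "segment")
    for (i in seq_len(nrow(objects))) {
      if (identical(type[i], "segment")) {
        img <- add_segment(img, objects$x_px[i], objects$y_px[i],
                           objects$angle[i], objects$length_px[i],
                           objects$thickness_px[i], objects$intensity[i])
      } else {
        img <- add_disc(img, objects$x_px[i], objects$y_px[i],
                        objects$radius_px[i], objects$intensity[i])
      }
    }
  }
  sigma_px <- um_to_px(psf_sigma, calibration)
  if (sigma_px > 0 && any(img > 0)) {
    img <- as.matrix(EBImage::imageData(EBImage::gblur(
      EBImage::Image(img), sigma = sigma_px)))
  }
  img + background
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Place n cell centres on a jittered grid, non-overlapping. Errors if the
# image cannot hold them after bounded retries.
place_cells <- function(n, dim, radius_px, max_tries = 500) {
  margin <- radius_px * 1.1
  lo <- margin + 1; hix <- dim[1] - margin; hiy <- dim[2] - margin
  if (hix <= lo || hiy <= lo)
    stop("image too small to place ", n, " cells of radius ", radius_px,
         " px", call. = FALSE)
  centres <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(stats::runif(1, lo, hix), stats::runif(1, lo, hiy))
      if (i == 1 ||
          all(sqrt(rowSums((centres[seq_len(i - 1), , drop = FALSE] -
                            matrix(cand, i - 1, 2, byrow = TRUE))^2)) >
              2.05 * radius_px)) {
        centres[i, ] <- cand; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("could not place ", n, " non-overlapping cells in a ",
           dim[1], "x", dim[2], " image after ", max_tries,
           " retries; enlarge the image", call. = FALSE)
  }
  centres
}

#' Generate a synthetic fixed-cell scene with known ground truth
#'
#' Simulates a multi-channel fluorescence image of HeLa-like cells, each with
#' one off-centre elliptical nucleus, organelle fragments placed at controlled
#' angular concentration about the nucleus-to-cell-centroid axis, and optional
#' uniformly placed puncta (endosome/lysosome-like structures). The scene
#' carries full ground truth (cell and nucleus label maps, fragment and puncta
#' centroids) so downstream segmentation and scoring can be validated exactly.
#' Identical arguments and seed produce bit-identical output.
#'
#' @param n_cells Number of cells (>= 1).
#' @param dispersion A [golgi_spec()] controlling fragment number and angular
#'   concentration.
#' @param puncta_count Puncta per cell (default 0 = none).
#' @param noise_sd Standard deviation of additive Gaussian read noise applied
#'   after rendering (0 = clean).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param calibration An [image_calibration()].
#' @param image_size Length-2 pixel dimensions; defaults to a square just
#'   large enough for `n_cells`.
#' @param cell_radius Mean cell radius in micrometres.
#' @param puncta_intensity_mean Mean puncta amplitude (arbitrary units).
#' @param render If `FALSE`, skip channel rendering and return ground truth
#'   only (fast path for statistical simulations on truth objects).
#' @param psf_sigma Gaussian PSF sigma in micrometres used for rendering.
#' @param background Constant background added to every channel.
#' @return A `scene_bundle`: list with `channels` (named list of matrices:
#'   `nuclei`, `cell`, `marker`, and `puncta` when requested), `calibration`,
#'   `cells` (tibble: cell_id, x_px, y_px, nuc_x_px, nuc_y_px, radius_um,
#'   ref_angle), `cell_labels`/`nucleus_labels` (integer matrices),
#'   `fragments` and `puncta` tibbles (cell_id, fragment_id, x_px, y_px,
#'   radius_um, area_px, intensity, angle_truth).
#' @export
generate_cell_scene <- function(n_cells, dispersion = golgi_spec(),
                                puncta_count = 0, noise_sd = 0, seed = 1,
                                calibration = image_calibration(),
                                image_size = NULL,
                                cell_radius = 8,
                                puncta_intensity_mean = 150,
                                render = TRUE, psf_sigma = 0.15,
                                background = 100) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  stopifnot(inherits(dispersion, "golgi_spec"), puncta_count >= 0,
            noise_sd >= 0)
  if (max(dispersion$radial_range) > cell_radius)
    stop("radial_range may not exceed the cell radius", call. = FALSE)
  r_px <- um_to_px(cell_radius, calibration)
  if (is.null(image_size)) {
    side <- ceiling(sqrt(n_cells))
    image_size <- rep(ceiling(side * 2.9 * r_px + 2 * r_px), 2)
  }
  withr::with_seed(seed, {
    centres <- place_cells(n_cells, image_size, r_px)
    cell_labels <- matrix(0L, image_size[1], image_size[2])
    nucleus_labels <- matrix(0L, image_size[1], image_size[2])
    cells <- vector("list", n_cells)
    frags <- vector("list", n_cells)
    puncta <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      cx <- centres[i, 1]; cy <- centres[i, 2]
      # perturbed-ellipse boundary: low-order angular harmonics on the radius
      ecc <- stats::runif(1, 0.85, 1.15)
      a1 <- stats::runif(1, 0, 0.06); a2 <- stats::runif(1, 0, 0.06)
      p1 <- stats::runif(1, -pi, pi); p2 <- stats::runif(1, -pi, pi)
      ecc_phase <- stats::runif(1, -pi, pi)
      rfun <- function(th) {
        base <- r_px * sqrt(1 / ((cos(th - ecc_phase) / ecc)^2 +
                                   (sin(th - ecc_phase) * ecc)^2))
        base * (1 + a1 * cos(th + p1) + a2 * cos(2 * th + p2))
      }
      rb <- rasterize_boundary(image_size, cx, cy, rfun, rmax = 1.4 * r_px)
      patch <- cell_labels[rb$xs, rb$ys]
      patch[rb$inside & patch == 0L] <- i
      cell_labels[rb$xs, rb$ys] <- patch
      # off-centre nucleus
      nuc_dir <- stats::runif(1, -pi, pi)
      nd <- 0.35 * r_px
      ncx <- cx + nd * cos(nuc_dir); ncy <- cy + nd * sin(nuc_dir)
      nr <- 0.33 * r_px
      necc <- stats::runif(1, 0.85, 1.15)
      nfun <- function(th) nr * sqrt(1 / ((cos(th) / necc)^2 +
                                            (sin(th) * necc)^2))
      nb <- rasterize_boundary(image_size, ncx, ncy, nfun, rmax = 1.4 * nr)
      npatch <- nucleus_labels[nb$xs, nb$ys]
      npatch[nb$inside & cell_labels[nb$xs, nb$ys] == i] <- i
      nucleus_labels[nb$xs, nb$ys] <- npatch
      # juxtanuclear reference: nucleus centroid -> cell centroid axis
      ref_angle <- atan2(cy - ncy, cx - ncx)
      cells[[i]] <- tibble::tibble(
        cell_id = i, x_px = cx, y_px = cy, nuc_x_px = ncx, nuc_y_px = ncy,
        radius_um = cell_radius, ref_angle = ref_angle)
      frags[[i]] <- sample_fragments(dispersion, cx, cy, ref_angle,
                                     cell_labels, calibration, cell_id = i)
      if (puncta_count > 0) {
        puncta[[i]] <- sample_puncta(puncta_count, cx, cy,
                                     0.9 * min(dispersion$radial_range[2],
                                               cell_radius * 0.8),
                                     cell_labels, calibration,
                                     puncta_intensity_mean, cell_id = i)
      }
    }
    cells <- dplyr::bind_rows(cells)
    fragments <- dplyr::bind_rows(frags)
    puncta <- if (puncta_count > 0) dplyr::bind_rows(puncta) else
      tibble::tibble()
    channels <- NULL
    if (render) {
      nuc_objs <- dplyr::transmute(cells, x_px = nuc_x_px, y_px = nuc_y_px,
                                   radius_px = 0.33 * r_px, intensity = 150,
                                   type = "disc")
      channels <- list(
        nuclei = render_channel(nuc_objs, image_size, psf_sigma, background,
                                calibration),
        cell = (cell_labels > 0) * 60 + background,
        marker = render_channel(
          dplyr::transmute(fragments, x_px, y_px,
                           radius_px = um_to_px(radius_um, calibration),
                           intensity, type = "disc"),
          image_size, psf_sigma, background, calibration))
      if (puncta_count > 0) {
        channels$puncta <- render_channel(
          dplyr::transmute(puncta, x_px, y_px,
                           radius_px = um_to_px(radius_um, calibration),
                           intensity, type = "disc"),
          image_size, psf_sigma, background, calibration)
      }
      if (noise_sd > 0) {
        channels <- lapply(channels, function(ch)
          ch + matrix(stats::rnorm(length(ch), 0, noise_sd),
                      nrow(ch), ncol(ch)))
      }
    }
    structure(list(channels = channels, calibration = calibration,
                   cells = cells, cell_labels = cell_labels,
                   nucleus_labels = nucleus_labels, fragments = fragments,
                   puncta = puncta, tracks = NULL, seed = seed),
              class = "scene_bundle")
  })
}

sample_fragments <- function(spec, cx, cy, ref_angle, cell_labels,
                             calibration, cell_id) {
  n <- spec$n_fragments
  if (n == 0) {
    return(tibble::tibble(cell_id = integer(), fragment_id = integer(),
                          x_px = numeric(), y_px = numeric(),
                          radius_um = numeric(), area_px = numeric(),
                          intensity = numeric(), angle_truth = numeric()))
  }
  out <- matrix(NA_real_, n, 4) # x, y, angle, r_um
  min_sep_px <- um_to_px(spec$min_separation, calibration)
  for (j in seq_len(n)) {
    for (try in seq_len(200)) {
      th <- rwrapped(1, ref_angle, spec$kappa)
      rad <- stats::runif(1, spec$radial_range[1], spec$radial_range[2])
      x <- cx + um_to_px(rad, calibration) * cos(th)
      y <- cy + um_to_px(rad, calibration) * sin(th)
      xi <- round(x); yi <- round(y)
      ok <- xi >= 1 && yi >= 1 && xi <= nrow(cell_labels) &&
        yi <= ncol(cell_labels) && cell_labels[xi, yi] == cell_id
      if (ok && min_sep_px > 0 && j > 1) {
        prev <- out[seq_len(j - 1), , drop = FALSE]
        ok <- all((prev[, 1] - x)^2 + (prev[, 2] - y)^2 >= min_sep_px^2)
      }
      if (ok) {
        out[j, ] <- c(x, y, th, rad); break
      }
    }
    if (is.na(out[j, 1]))
      stop("failed to place fragment inside cell mask; radial_range or ",
           "min_separation too demanding for this cell geometry",
           call. = FALSE)
  }
  frad <- stats::runif(n, spec$fragment_radius_range[1],
                       spec$fragment_radius_range[2])
  tibble::tibble(
    cell_id = cell_id, fragment_id = seq_len(n),
    x_px = out[, 1], y_px = out[, 2], radius_um = frad,
    area_px = pi * um_to_px(frad, calibration)^2,
    intensity = spec$intensity_mean * stats::runif(n, 0.8, 1.2),
    angle_truth = out[, 3])
}

sample_puncta <- function(n, cx, cy, max_r_um, cell_labels, calibration,
                          intensity_mean, cell_id) {
  out <- matrix(NA_real_, n, 2)
  for (j in seq_len(n)) {
    for (try in seq_len(100)) {
      th <- stats::runif(1, -pi, pi)
      rad <- max_r_um * sqrt(stats::runif(1))
      x <- cx + um_to_px(rad, calibration) * cos(th)
      y <- cy + um_to_px(rad, calibration) * sin(th)
      xi <- round(x); yi <- round(y)
      if (xi >= 1 && yi >= 1 && xi <= nrow(cell_labels) &&
          yi <= ncol(cell_labels) && cell_labels[xi, yi] == cell_id) {
        out[j, ] <- c(x, y); break
      }
    }
    if (is.na(out[j, 1]))
      stop("failed to place punctum inside cell mask", call. = FALSE)
  }
  frad <- stats::runif(n, 0.12, 0.25)
  tibble::tibble(
    cell_id = cell_id, fragment_id = seq_len(n),
    x_px = out[, 1], y_px = out[, 2], radius_um = frad,
    area_px = pi * um_to_px(frad, calibration)^2,
    intensity = intensity_mean * stats::runif(n, 0.8, 1.2),
    angle_truth = NA_real_)
}

#' Generate a synthetic carrier time-lapse with known tracks
#'
#' Simulates a 2D time-lapse of moving membrane carriers. Straight-path
#' carriers advance `speed * frame_interval` micrometres per frame along a
#' fixed heading; random-walk carriers redraw the heading every frame. Tubular
#' carriers (`length > 0`) are rendered as line segments oriented along the
#' heading. Truth tracks record exact sub-pixel positions per frame; a carrier
#' that leaves the field of view has its track truncated and flagged
#' (`left_fov = TRUE`), never an error.
#'
#' @param specs A [carrier_spec()] or list of them.
#' @param n_frames Number of frames (>= 2).
#' @param calibration An [image_calibration()].
#' @param noise_sd Additive Gaussian noise sd (0 = clean).
#' @param seed Integer seed.
#' @param image_size Length-2 pixel dimensions (default 512 x 512).
#' @param psf_sigma PSF sigma in micrometres.
#' @param background Constant background intensity.
#' @param render If `FALSE`, return truth tracks only.
#' @return A `scene_bundle` whose `channels$carrier` is an x-y-time array and
#'   whose `tracks` tibble has columns carrier_id, frame, x_px, y_px, x_um,
#'   y_um, angle, length_um, in_fov, left_fov.
#' @export
generate_timelapse <- function(specs, n_frames, calibration = image_calibration(),
                               noise_sd = 0, seed = 1,
                               image_size = c(512, 512), psf_sigma = 0.15,
                               background = 20, render = TRUE) {
  if (inherits(specs, "carrier_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "carrier_spec")))
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  fov_um <- px_to_um(image_size, calibration)
  withr::with_seed(seed, {
    tracks <- list(); cid <- 0L
    for (sp in specs) {
      for (k in seq_len(sp$n_carriers)) {
        cid <- cid + 1L
        pos <- if (!is.null(sp$start_positions)) sp$start_positions[k, ] else
          c(stats::runif(1, 0.15, 0.85) * fov_um[1],
            stats::runif(1, 0.15, 0.85) * fov_um[2])
        heading <- stats::runif(1, -pi, pi)
        step <- sp$speed * calibration$frame_interval
        P <- matrix(NA_real_, n_frames, 2); A <- numeric(n_frames)
        P[1, ] <- pos; A[1] <- heading
        for (f in 2:n_frames) {
          if (sp$path == "random-walk") heading <- stats::runif(1, -pi, pi)
          pos <- pos + step * c(cos(heading), sin(heading))
          P[f, ] <- pos; A[f] <- heading
        }
        in_fov <- P[, 1] >= 0 & P[, 1] <= fov_um[1] &
          P[, 2] >= 0 & P[, 2] <= fov_um[2]
        # truncate at first exit: later re-entries are not followed
        first_out <- which(!in_fov)[1]
        keep <- if (is.na(first_out)) seq_len(n_frames) else
          seq_len(first_out - 1L)
        tracks[[cid]] <- tibble::tibble(
          carrier_id = cid, frame = keep,
          x_um = P[keep, 1], y_um = P[keep, 2],
          x_px = um_to_px(P[keep, 1], calibration),
          y_px = um_to_px(P[keep, 2], calibration),
          angle = A[keep], length_um = sp$length,
          intensity = sp$intensity,
          in_fov = TRUE, left_fov = !is.na(first_out))
      }
    }
    tracks <- dplyr::bind_rows(tracks)
    channels <- NULL
    if (render) {
      arr <- array(0, dim = c(image_size[1], image_size[2], n_frames))
      thick_px <- um_to_px(0.3, calibration)
      for (f in seq_len(n_frames)) {
        det <- dplyr::filter(tracks, .data$frame == f)
        objs <- dplyr::transmute(
          det, x_px, y_px, intensity,
          radius_px = ifelse(length_um > 0, NA_real_,
                             um_to_px(0.15, calibration)),
          length_px = um_to_px(length_um, calibration),
          angle, thickness_px = thick_px,
          type = ifelse(length_um > 0, "segment", "disc"))
        fr <- render_channel(objs, image_size, psf_sigma, background,
                             calibration)
        if (noise_sd > 0)
          fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sd),
                            nrow(fr), ncol(fr))
        arr[, , f] <- fr
      }
      channels <- list(carrier = arr)
    }
    structure(list(channels = channels, calibration = calibration,
                   cells = NULL, cell_labels = NULL, nucleus_labels = NULL,
                   fragments = NULL, puncta = NULL, tracks = tracks,
                   seed = seed),
              class = "scene_bundle")
  })
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat("<scene_bundle>\n")
  if (!is.null(x$channels))
    cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (!is.null(x$cells)) cat("  cells:", nrow(x$cells), "\n")
  if (!is.null(x$fragments)) cat("  fragments:", nrow(x$fragments), "\n")
  if (!is.null(x$tracks))
    cat("  tracks:", dplyr::n_distinct(x$tracks$carrier_id), "carriers,",
        max(x$tracks$frame), "frames\n")
  invisible(x)
}
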