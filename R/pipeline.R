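#' Simulate a multi-arm Golgi morphology screen
#'
#' Generates one synthetic scene per treatment arm, each with its own
#' fragment count and angular concentration, and labels the cells with the
#' arm's treatment. Fragmentation phenotypes are emulated by raising
#' `n_fragments` while lowering `kappa`; compaction by the reverse.
#'
#' @param arms Tibble with one row per arm: `treatment`, `n_cells`,
#'   `n_fragments`, `kappa` (a `NEG` row is the usual control).
#' @param seed Integer master seed; each arm derives its own sub-seed.
#' @param render Render channels (`TRUE`) or ground truth only (`FALSE`,
#'   fast; the default — statistical simulations need no pixels).
#' @param noise_sd Read-noise sd passed through to the generator.
#' @param calibration An [image_calibration()].
#' @return Named list of `scene_bundle`s, one per treatment, with a
#'   `treatment` column added to each scene's `cells`.
#' @export
simulate_golgi_screen <- function(arms, seed = 1, render = FALSE,
                                  noise_sd = 0,
                                  calibration = image_calibration()) {
  stopifnot(all(c("treatment", "n_cells", "n_fragments", "kappa") %in%
                  names(arms)))
  scenes <- list()
  for (i in seq_len(nrow(arms))) {
    sp <- golgi_spec(
      n_fragments = arms$n_fragments[i], kappa = arms$kappa[i],
      min_separation = if ("min_separation" %in% names(arms))
        arms$min_separation[i] else 0)
    sc <- generate_cell_scene(arms$n_cells[i], dispersion = sp,
                              noise_sd = noise_sd,
                              seed = (seed * 1009 + i * 7919) %% .Machine$integer.max,
                              calibration = calibration, render = render)
    sc$cells$treatment <- arms$treatment[i]
    scenes[[arms$treatment[i]]] <- sc
  }
  scenes
}

#' Score a Golgi morphology screen
#'
#' Runs the fixed-cell analysis end to end over a named list of scenes (one
#' per treatment): per-cell fragment detection (or the ground-truth bypass),
#' per-cell polar distribution scores and feature extraction, per-treatment
#' normalization to the negative control, Mann-Whitney tests against the
#' control, and the screen-level correlation between normalized fragment
#' count and normalized PDS.
#'
#' @param scenes Named list of `scene_bundle`s, names = treatments (or
#'   scenes whose `cells` carry a `treatment` column).
#' @param control Negative-control treatment label (default `"NEG"`).
#' @param mode `"truth"` scores ground-truth objects; `"segment"` runs
#'   nuclei/cell segmentation and fragment detection on the rendered
#'   channels.
#' @param center Centre for the polar conversion: `"cell"` or `"nucleus"`.
#' @param n_bins Angular sectors for the PDS (default 8).
#' @param min_area_px,k Fragment-detection parameters (segment mode).
#' @return An object of class `golgi_screen`: list with `per_cell` (tibble of
#'   cell-level pds + features), `per_treatment` (normalized means),
#'   `tests` (Mann-Whitney vs control on PDS and fragment count),
#'   `correlation_r`, and `control`.
#' @export
score_golgi_screen <- function(scenes, control = "NEG",
                               mode = c("truth", "segment"),
                               center = c("cell", "nucleus"), n_bins = 8,
                               min_area_px = 4, k = 3) {
  mode <- match.arg(mode); center <- match.arg(center)
  if (length(scenes) == 0) stop("empty image set", call. = FALSE)
  if (inherits(scenes, "scene_bundle")) scenes <- list(scenes)
  per_cell <- list()
  offset <- 0L
  for (nm in seq_along(scenes)) {
    sc <- scenes[[nm]]
    trt <- sc$cells$treatment %||% names(scenes)[nm]
    if (mode == "truth") {
      cells <- sc$cells
      frags <- sc$fragments
    } else {
      if (is.null(sc$channels))
        stop("segment mode needs rendered channels", call. = FALSE)
      nuc <- segment_nuclei(sc$channels$nuclei)
      cl <- segment_cells(nuc, sc$channels$cell)
      cells <- cell_table(cl, nuc)
      frags <- detect_fragments(cl, sc$channels$marker,
                                min_area_px = min_area_px, k = k)
    }
    cells$treatment <- trt
    scored <- pds_by_cell(frags, cells, center = center, n_bins = n_bins)
    feats <- cell_features(cells, frags, sc$calibration)
    tab <- dplyr::left_join(
      scored, dplyr::select(feats, -dplyr::any_of("treatment")),
      by = "cell_id")
    tab$cell_id <- tab$cell_id + offset
    offset <- offset + max(cells$cell_id, 0L)
    per_cell[[nm]] <- tab
  }
  per_cell <- dplyr::bind_rows(per_cell)
  if (!control %in% per_cell$treatment)
    stop("control treatment '", control, "' missing from screen",
         call. = FALSE)
  pds_norm <- normalize_pds(per_cell, control = control)
  count_norm <- normalize_features(
    dplyr::select(per_cell, "treatment", "n_structures"),
    control = control, feature_cols = "n_structures")
  per_treatment <- dplyr::left_join(
    pds_norm, dplyr::select(count_norm, "treatment",
                            norm_fragment_count = "n_structures_norm",
                            mean_fragment_count = "n_structures_mean"),
    by = "treatment")
  tests <- list(
    pds = mann_whitney_vs_control(per_cell, "pds", "treatment", control),
    fragment_count = mann_whitney_vs_control(per_cell, "n_structures",
                                             "treatment", control))
  r <- if (nrow(per_treatment) >= 3) {
    pearson_correlation(per_treatment$norm_fragment_count,
                        per_treatment$normalized_pds)
  } else NA_real_
  structure(list(per_cell = per_cell, per_treatment = per_treatment,
                 tests = tests, correlation_r = r, control = control),
            class = "golgi_screen")
}

#' Simulate a multi-arm carrier-motility screen
#'
#' One time-lapse video per treatment arm, carriers moving at the arm's
#' programmed speed. A depletion phenotype is emulated by scaling the speed
#' relative to the control arm.
#'
#' @param arms Tibble: `treatment`, `n_carriers`, `speed` (µm/s), and
#'   optionally `length` (µm, default 0) and `n_frames` (default 60).
#' @param seed Integer master seed.
#' @param noise_sd Read-noise sd.
#' @param image_size Pixel dimensions of each video frame.
#' @param calibration An [image_calibration()].
#' @return Named list of time-lapse `scene_bundle`s.
#' @export
simulate_carrier_screen <- function(arms, seed = 1, noise_sd = 0,
                                    image_size = c(512, 512),
                                    calibration = image_calibration()) {
  stopifnot(all(c("treatment", "n_carriers", "speed") %in% names(arms)))
  videos <- list()
  for (i in seq_len(nrow(arms))) {
    sp <- carrier_spec(
      n_carriers = arms$n_carriers[i], speed = arms$speed[i],
      length = if ("length" %in% names(arms)) arms$length[i] else 0)
    nf <- if ("n_frames" %in% names(arms)) arms$n_frames[i] else 60
    videos[[arms$treatment[i]]] <- generate_timelapse(
      sp, n_frames = nf, calibration = calibration, noise_sd = noise_sd,
      seed = (seed * 2003 + i * 6007) %% .Machine$integer.max,
      image_size = image_size)
  }
  videos
}

#' Analyse a carrier-motility screen
#'
#' Per video: preprocess the stack, detect carriers per frame, link
#' nearest-neighbour tracks, compute per-track speed and displacement, and
#' keep tracks displacing more than the cutoff. Arm summaries report mean
#' speed and displacement as percentages of the negative-control arm.
#'
#' @param videos Named list of time-lapse `scene_bundle`s (names =
#'   treatments), or bare x-y-time arrays.
#' @param control Negative-control label (default `"NEG"`).
#' @param calibration Used for bare arrays; scenes carry their own.
#' @param preprocess Apply the subtract/blur/multiply recipe first
#'   (default TRUE).
#' @param min_displacement Track displacement cutoff in µm (strict `>`).
#' @param max_step Linker step limit, µm per frame.
#' @return An object of class `carrier_screen`: `per_track` tibble,
#'   `per_treatment` summary (mean speed/displacement and percent-of-control
#'   columns), `control`.
#' @export
track_carrier_screen <- function(videos, control = "NEG",
                                 calibration = image_calibration(),
                                 preprocess = TRUE, min_displacement = 2,
                                 max_step = 1.5) {
  if (length(videos) == 0) stop("no videos", call. = FALSE)
  if (!control %in% names(videos))
    stop("control arm '", control, "' missing", call. = FALSE)
  per_track <- list()
  for (nm in names(videos)) {
    v <- videos[[nm]]
    cal <- if (inherits(v, "scene_bundle")) v$calibration else calibration
    arr <- if (inherits(v, "scene_bundle")) v$channels$carrier else v
    if (is.null(arr)) stop("video '", nm, "' has no carrier channel",
                           call. = FALSE)
    if (length(dim(arr)) != 3 || dim(arr)[3] < 2)
      stop("video '", nm, "' must have >= 2 frames", call. = FALSE)
    if (preprocess) arr <- preprocess_stack(arr)
    dets <- lapply(seq_len(dim(arr)[3]), function(f) {
      d <- detect_carriers(arr[, , f], cal)
      if (nrow(d)) d$frame <- f
      d
    })
    dets <- dplyr::bind_rows(dets)
    if (nrow(dets) == 0 || length(unique(dets$frame)) < 2) next
    linked <- link_tracks(dets, cal, max_step = max_step)
    st <- track_statistics(linked, cal)
    st <- filter_tracks(st, min_displacement = min_displacement)
    if (nrow(st)) st$treatment <- nm
    per_track[[nm]] <- st
  }
  per_track <- dplyr::bind_rows(per_track)
  if (nrow(per_track) == 0) stop("no tracks survived filtering",
                                 call. = FALSE)
  per_treatment <- dplyr::summarise(
    dplyr::group_by(per_track, .data$treatment),
    n_tracks = dplyr::n(),
    mean_speed_um_s = mean(.data$mean_speed_um_s),
    mean_displacement_um = mean(.data$displacement_um),
    .groups = "drop")
  ctrl <- dplyr::filter(per_treatment, .data$treatment == control)
  if (nrow(ctrl) == 0)
    stop("control arm '", control, "' yielded no tracks", call. = FALSE)
  per_treatment <- dplyr::mutate(
    per_treatment,
    pct_speed_of_control = 100 * .data$mean_speed_um_s /
      ctrl$mean_speed_um_s,
    pct_displacement_of_control = 100 * .data$mean_displacement_um /
      ctrl$mean_displacement_um)
  structure(list(per_track = per_track, per_treatment = per_treatment,
                 control = control),
            class = "carrier_screen")
}

#' @export
print.golgi_screen <- function(x, ...) {
  cat("<golgi_screen>", nrow(x$per_treatment), "treatments,",
      nrow(x$per_cell), "cells; control =", x$control, "\n")
  cat("  normalized fragment count vs normalized PDS: r =",
      round(x$correlation_r, 3), "\n")
  print(x$per_treatment)
  invisible(x)
}

#' @export
print.carrier_screen <- function(x, ...) {
  cat("<carrier_screen>", nrow(x$per_treatment), "arms,",
      nrow(x$per_track), "tracks; control =", x$control, "\n")
  print(x$per_treatment)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-treatment summary of a Golgi screen
#'
#' @param x A `golgi_screen`.
#' @param ... Unused.
#' @return Per-treatment tibble with normalized means joined to the adjusted
#'   Mann-Whitney p-values on PDS and fragment count.
#' @method tidy golgi_screen
#' @export
tidy.golgi_screen <- function(x, ...) {
  out <- dplyr::left_join(
    x$per_treatment,
    dplyr::select(x$tests$pds, "treatment", pds_p_adjusted = "p_adjusted",
                  pds_stars = "stars"),
    by = "treatment")
  dplyr::left_join(
    out,
    dplyr::select(x$tests$fragment_count, "treatment",
                  count_p_adjusted = "p_adjusted", count_stars = "stars"),
    by = "treatment")
}

#' @rdname tidy.golgi_screen
#' @method tidy carrier_screen
#' @export
tidy.carrier_screen <- function(x, ...) x$per_treatment

#' One-row summary of a Golgi screen
#'
#' @param x A `golgi_screen`.
#' @param ... Unused.
#' @return Tibble: `n_treatments`, `n_cells`, `correlation_r`, `control`.
#' @method glance golgi_screen
#' @export
glance.golgi_screen <- function(x, ...) {
  tibble::tibble(n_treatments = nrow(x$per_treatment),
                 n_cells = nrow(x$per_cell),
                 correlation_r = x$correlation_r, control = x$control)
}

#' @rdname glance.golgi_screen
#' @method glance carrier_screen
#' @export
glance.carrier_screen <- function(x, ...) {
  tibble::tibble(n_treatments = nrow(x$per_treatment),
                 n_tracks = nrow(x$per_track), control = x$control)
}
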