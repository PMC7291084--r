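#' Write a scene to disk as TIFF + CSV ground truth
#'
#' Writes every channel as a 32-bit grayscale TIFF (one page per frame for
#' time-lapse channels), intensities scaled into `[0, 1]` by a per-scene
#' scale recorded in the config sidecar; truth label maps as 16-bit TIFF;
#' ground-truth objects and cells as CSV; and a flat `key: value` config file
#' recording the seed, calibration and intensity scale. Deterministic: the
#' same scene writes byte-identical files.
#'
#' @param scene A `scene_bundle`.
#' @param dir Output directory (created if needed).
#' @param name Basename prefix for all files.
#' @param overwrite Allow clobbering existing files (default `FALSE`).
#' @return Invisibly, a character vector of the files written.
#' @export
write_scene <- function(scene, dir, name = "scene", overwrite = FALSE) {
  stopifnot(inherits(scene, "scene_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  path_of <- function(suffix) {
    p <- file.path(dir, paste0(name, "_", suffix))
    if (file.exists(p) && !overwrite)
      stop("file exists: ", p, " (use overwrite = TRUE)", call. = FALSE)
    paths <<- c(paths, p)
    p
  }
  scale <- 1
  if (!is.null(scene$channels)) {
    scale <- max(1, vapply(scene$channels, max, numeric(1)))
    for (ch in names(scene$channels)) {
      arr <- scene$channels[[ch]]
      pages <- if (length(dim(arr)) == 3)
        lapply(seq_len(dim(arr)[3]), function(f) t(arr[, , f]) / scale)
      else list(t(arr) / scale)
      tiff::writeTIFF(pages, path_of(paste0(ch, ".tif")),
                      bits.per.sample = 32, reduce = FALSE)
    }
  }
  for (lb in c("cell_labels", "nucleus_labels")) {
    if (!is.null(scene[[lb]])) {
      tiff::writeTIFF(t(scene[[lb]]) / 65535, path_of(paste0(lb, ".tif")),
                      bits.per.sample = 16, reduce = FALSE)
    }
  }
  truth <- truth_objects(scene)
  readr::write_csv(truth, path_of("truth.csv"))
  if (!is.null(scene$cells))
    readr::write_csv(scene$cells, path_of("cells.csv"))
  cfg <- c(seed = scene$seed,
           pixel_size = scene$calibration$pixel_size,
           frame_interval = scene$calibration$frame_interval,
           intensity_scale = scale)
  writeLines(paste0(names(cfg), ": ", format(cfg, digits = 17,
                                             scientific = FALSE)),
             path_of("config.txt"))
  invisible(paths)
}

# Flatten scene truth into the sidecar schema:
# object_id, cell_id, frame, x_px, y_px, area_px, type
truth_objects <- function(scene) {
  parts <- list()
  if (!is.null(scene$fragments) && nrow(scene$fragments) > 0)
    parts$frag <- dplyr::transmute(
      scene$fragments, object_id = dplyr::row_number(), cell_id,
      frame = NA_integer_, x_px, y_px, area_px, type = "fragment")
  if (!is.null(scene$puncta) && nrow(scene$puncta) > 0)
    parts$punc <- dplyr::transmute(
      scene$puncta, object_id = dplyr::row_number(), cell_id,
      frame = NA_integer_, x_px, y_px, area_px, type = "punctum")
  if (!is.null(scene$tracks) && nrow(scene$tracks) > 0)
    parts$trk <- dplyr::transmute(
      scene$tracks, object_id = carrier_id, cell_id = NA_integer_, frame,
      x_px, y_px, area_px = NA_real_, type = "carrier")
  if (length(parts) == 0)
    return(tibble::tibble(object_id = integer(), cell_id = integer(),
                          frame = integer(), x_px = numeric(),
                          y_px = numeric(), area_px = numeric(),
                          type = character()))
  dplyr::bind_rows(parts)
}

#' Read a scene written by [write_scene()]
#'
#' Reconstructs the channels (rescaled by the recorded intensity scale),
#' truth label maps, truth tables and calibration.
#'
#' @param dir Directory holding the files.
#' @param name Basename prefix used at write time.
#' @return A `scene_bundle` (channels, calibration, cells, labels, truth
#'   tables; tracks are restored from the truth CSV for time-lapse scenes).
#' @export
read_scene <- function(dir, name = "scene") {
  cfg_path <- file.path(dir, paste0(name, "_config.txt"))
  if (!file.exists(cfg_path)) stop("no config at ", cfg_path, call. = FALSE)
  cfg_lines <- strsplit(readLines(cfg_path), ": ", fixed = TRUE)
  cfg <- stats::setNames(
    as.numeric(trimws(vapply(cfg_lines, `[`, "", 2))),
    vapply(cfg_lines, `[`, "", 1))
  cal <- image_calibration(cfg[["pixel_size"]], cfg[["frame_interval"]])
  scale <- cfg[["intensity_scale"]]
  known <- c("truth", "cells", "config", "cell_labels", "nucleus_labels")
  tifs <- list.files(dir, pattern = paste0("^", name, "_.*\\.tif$"))
  ch_names <- setdiff(sub(paste0("^", name, "_(.*)\\.tif$"), "\\1", tifs),
                      known)
  channels <- list()
  for (ch in ch_names) {
    pages <- tiff::readTIFF(file.path(dir, paste0(name, "_", ch, ".tif")),
                            all = TRUE)
    mats <- lapply(pages, function(p) t(p) * scale)
    channels[[ch]] <- if (length(mats) == 1) mats[[1]] else
      array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  }
  labs <- list(cell_labels = NULL, nucleus_labels = NULL)
  for (lb in names(labs)) {
    p <- file.path(dir, paste0(name, "_", lb, ".tif"))
    if (file.exists(p)) {
      m <- t(tiff::readTIFF(p)) * 65535
      m <- matrix(as.integer(round(m)), nrow(m), ncol(m))
      labs[[lb]] <- m
    }
  }
  truth <- readr::read_csv(file.path(dir, paste0(name, "_truth.csv")),
                           show_col_types = FALSE)
  cells_path <- file.path(dir, paste0(name, "_cells.csv"))
  cells <- if (file.exists(cells_path))
    readr::read_csv(cells_path, show_col_types = FALSE) else NULL
  fragments <- dplyr::filter(truth, .data$type == "fragment")
  puncta <- dplyr::filter(truth, .data$type == "punctum")
  tracks <- dplyr::filter(truth, .data$type == "carrier")
  if (nrow(tracks) > 0)
    tracks <- dplyr::rename(tracks, carrier_id = "object_id")
  structure(list(channels = if (length(channels)) channels else NULL,
                 calibration = cal, cells = cells,
                 cell_labels = labs$cell_labels,
                 nucleus_labels = labs$nucleus_labels,
                 fragments = fragments, puncta = puncta,
                 tracks = if (nrow(tracks)) tracks else NULL,
                 seed = unname(cfg[["seed"]])),
            class = "scene_bundle")
}
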