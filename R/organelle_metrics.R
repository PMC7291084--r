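#' Count detected structures per cell
#'
#' Number of fragments surviving the size filter, per cell. An empty fragment
#' table yields a zero count for every cell listed in `cell_ids`.
#'
#' @param fragments Per-fragment tibble (columns `cell_id`, `fragment_id`).
#' @param cell_ids Optional vector of cell ids to report (so cells with zero
#'   fragments appear with count 0).
#' @return A tibble: `cell_id`, `n_structures`.
#' @export
count_structures <- function(fragments, cell_ids = NULL) {
  counts <- if (is.null(fragments) || nrow(fragments) == 0)
    tibble::tibble(cell_id = integer(), n_structures = integer())
  else dplyr::summarise(dplyr::group_by(fragments, .data$cell_id),
                        n_structures = dplyr::n(), .groups = "drop")
  if (!is.null(cell_ids)) {
    counts <- dplyr::left_join(tibble::tibble(cell_id = cell_ids), counts,
                               by = "cell_id")
    counts$n_structures[is.na(counts$n_structures)] <- 0L
  }
  counts
}

#' Marker intensity over detected structures, per cell
#'
#' Sums the marker channel over each cell's structure pixels. The total is
#' the integrated intensity; the mean is total / structure pixel count. No
#' background subtraction is applied by default (an optional per-cell median
#' subtraction is available). A cell with zero structure pixels reports total
#' 0 and mean 0 with `no_structures = TRUE`.
#'
#' @param cell_labels Integer cell label matrix.
#' @param structure_mask Logical/0-1 matrix of detected structure pixels.
#' @param channel Numeric matrix of marker intensities.
#' @param subtract_median If `TRUE`, subtract each cell's median pixel value
#'   from the channel before integrating.
#' @return A tibble: `cell_id`, `total_intensity`, `mean_intensity`,
#'   `structure_px`, `no_structures`.
#' @export
intensity_per_cell <- function(cell_labels, structure_mask, channel,
                               subtract_median = FALSE) {
  stopifnot(all(dim(cell_labels) == dim(channel)),
            all(dim(structure_mask) == dim(channel)))
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  rows <- lapply(ids, function(id) {
    in_cell <- cell_labels == id
    ch <- channel
    if (subtract_median) ch <- ch - stats::median(ch[in_cell])
    sel <- in_cell & structure_mask > 0
    npx <- sum(sel)
    tot <- if (npx > 0) sum(ch[sel]) else 0
    tibble::tibble(cell_id = id, total_intensity = tot,
                   mean_intensity = if (npx > 0) tot / npx else 0,
                   structure_px = npx, no_structures = npx == 0)
  })
  dplyr::bind_rows(rows)
}

#' Area occupied by structures, per cell
#'
#' Sum of fragment areas converted to square micrometres via the pixel size.
#'
#' @param fragments Per-fragment tibble with `cell_id` and `area_px`.
#' @param calibration An [image_calibration()].
#' @param cell_ids Optional ids to report (zeros for fragment-free cells).
#' @return A tibble: `cell_id`, `occupied_area_px`, `occupied_area_um2`.
#' @export
occupied_area <- function(fragments, calibration = image_calibration(),
                          cell_ids = NULL) {
  areas <- if (is.null(fragments) || nrow(fragments) == 0)
    tibble::tibble(cell_id = integer(), occupied_area_px = numeric())
  else dplyr::summarise(dplyr::group_by(fragments, .data$cell_id),
                        occupied_area_px = sum(.data$area_px),
                        .groups = "drop")
  if (!is.null(cell_ids)) {
    areas <- dplyr::left_join(tibble::tibble(cell_id = cell_ids), areas,
                              by = "cell_id")
    areas$occupied_area_px[is.na(areas$occupied_area_px)] <- 0
  }
  dplyr::mutate(areas,
                occupied_area_um2 = .data$occupied_area_px *
                  calibration$pixel_size^2)
}

#' Assemble the per-cell feature table
#'
#' One row per cell: structure count, integrated and mean structure
#' intensity, and occupied area, from a fragment table.
#'
#' @param cells Per-cell tibble (from [cell_table()] or scene truth), with
#'   `cell_id` and optionally `treatment`.
#' @param fragments Per-fragment tibble with `cell_id`, `area_px`,
#'   `intensity`.
#' @param calibration An [image_calibration()].
#' @return A tibble: `cell_id`, `treatment` (if present), `n_structures`,
#'   `total_intensity`, `mean_intensity`, `occupied_area_um2`.
#' @export
cell_features <- function(cells, fragments,
                          calibration = image_calibration()) {
  counts <- count_structures(fragments, cell_ids = cells$cell_id)
  areas <- occupied_area(fragments, calibration, cell_ids = cells$cell_id)
  ints <- if (is.null(fragments) || nrow(fragments) == 0)
    tibble::tibble(cell_id = cells$cell_id, total_intensity = 0)
  else dplyr::summarise(dplyr::group_by(fragments, .data$cell_id),
                        total_intensity = sum(.data$intensity),
                        .groups = "drop")
  out <- dplyr::left_join(counts, ints, by = "cell_id")
  out$total_intensity[is.na(out$total_intensity)] <- 0
  out <- dplyr::left_join(out, dplyr::select(areas, "cell_id",
                                             "occupied_area_um2"),
                          by = "cell_id")
  out <- dplyr::mutate(out, mean_intensity = ifelse(
    .data$n_structures > 0, .data$total_intensity /
      pmax(1e-300, .data$occupied_area_um2 / calibration$pixel_size^2), 0))
  if ("treatment" %in% names(cells))
    out <- dplyr::left_join(out, dplyr::select(cells, "cell_id", "treatment"),
                            by = "cell_id")
  out
}

#' Normalize per-treatment feature means to the negative control
#'
#' For every numeric feature, the per-treatment mean is divided by the
#' negative-control mean of the same feature, the standard readout of
#' control-normalized high-content screens.
#'
#' @param features Per-cell tibble with a `treatment` column and one or more
#'   numeric feature columns.
#' @param control Control treatment label (default `"NEG"`).
#' @param feature_cols Character vector of columns to normalize; defaults to
#'   every numeric column except `cell_id`.
#' @return A tibble with one row per treatment: `treatment`, `n_cells`, then
#'   `<feature>_mean` and `<feature>_norm` per feature.
#' @export
normalize_features <- function(features, control = "NEG",
                               feature_cols = NULL) {
  stopifnot("treatment" %in% names(features))
  if (!control %in% features$treatment)
    stop("missing treatment rows for control '", control, "'", call. = FALSE)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(
      names(features)[vapply(features, is.numeric, logical(1))], "cell_id")
  }
  missing <- setdiff(feature_cols, names(features))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  means <- dplyr::summarise(
    dplyr::group_by(features, .data$treatment), n_cells = dplyr::n(),
    dplyr::across(dplyr::all_of(feature_cols), mean,
                  .names = "{.col}_mean"),
    .groups = "drop")
  ctrl <- dplyr::filter(means, .data$treatment == control)
  for (fc in feature_cols) {
    cm <- ctrl[[paste0(fc, "_mean")]]
    if (cm <= 0)
      stop("control mean of '", fc, "' is not positive; cannot normalize",
           call. = FALSE)
    means[[paste0(fc, "_norm")]] <- means[[paste0(fc, "_mean")]] / cm
  }
  means
}
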