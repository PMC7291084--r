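#' Segment nuclei from a nuclear-stain channel
#'
#' Global threshold (Otsu by default, or a fixed value), hole filling,
#' 4-connected labelling, and size filtering. Nuclei merged by blur can be
#' split by a distance-transform watershed (`declump = TRUE`).
#'
#' @param nucleus_channel 2D numeric matrix (single channel).
#' @param threshold Either `"otsu"` or a numeric intensity cutoff.
#' @param min_area_px Minimum object area kept (pixels).
#' @param declump If `TRUE`, split touching nuclei with a distance-transform
#'   watershed.
#' @return An integer label matrix; 0 is background. A constant image yields
#'   zero labels, not an error.
#' @export
segment_nuclei <- function(nucleus_channel, threshold = "otsu",
                           min_area_px = 50, declump = FALSE) {
  stopifnot(is.matrix(nucleus_channel))
  rng <- range(nucleus_channel)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(nucleus_channel),
                                      ncol(nucleus_channel)))
  thr <- if (identical(threshold, "otsu")) {
    scaled <- (nucleus_channel - rng[1]) / (rng[2] - rng[1])
    rng[1] + EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1])
  } else threshold
  mask <- nucleus_channel > thr
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  if (declump) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  filter_small_labels(lab, min_area_px)
}

filter_small_labels <- function(lab, min_area_px) {
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(sizes < min_area_px)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel(lab)
}

relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(lab)
  lut <- integer(max(ids)); lut[ids] <- seq_along(ids)
  lab[lab > 0] <- lut[lab[lab > 0]]
  lab
}

#' Segment cells by seeded propagation from nuclei
#'
#' Grows each nucleus seed through the cell-body foreground (thresholded
#' cytoplasm/actin channel) so that every cell label contains exactly one
#' nucleus and the cells partition the foreground. A nucleus with no
#' detectable surrounding cytoplasm is discarded with a warning. Cells
#' touching the image border are excluded when `exclude_border = TRUE`
#' (standard high-content practice).
#'
#' @param nuclei_labels Integer label matrix from [segment_nuclei()].
#' @param cell_channel 2D numeric matrix of a whole-cell stain.
#' @param threshold `"otsu"` or numeric cutoff defining the cell foreground.
#' @param exclude_border Drop cells touching the image border (default TRUE).
#' @return Integer cell label matrix; labels match the seeding nucleus labels
#'   (relabelled consecutively).
#' @export
segment_cells <- function(nuclei_labels, cell_channel, threshold = "otsu",
                          exclude_border = TRUE) {
  stopifnot(is.matrix(nuclei_labels), is.matrix(cell_channel),
            all(dim(nuclei_labels) == dim(cell_channel)))
  if (max(nuclei_labels) == 0)
    return(matrix(0L, nrow(cell_channel), ncol(cell_channel)))
  rng <- range(cell_channel)
  thr <- if (identical(threshold, "otsu")) {
    if (rng[1] == rng[2]) rng[1] else {
      scaled <- (cell_channel - rng[1]) / (rng[2] - rng[1])
      rng[1] + EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1])
    }
  } else threshold
  fg <- cell_channel > thr | nuclei_labels > 0
  lab <- EBImage::propagate(EBImage::Image(cell_channel),
                            EBImage::Image(nuclei_labels), mask = fg)
  lab <- as.matrix(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  # a seed that could not grow past itself has no cytoplasm: discard
  nuc_ids <- sort(unique(nuclei_labels[nuclei_labels > 0]))
  for (id in nuc_ids) {
    if (sum(lab == id) <= sum(nuclei_labels == id)) {
      warning("nucleus ", id, " has no detectable cytoplasm; cell discarded",
              call. = FALSE)
      lab[lab == id] <- 0L
    }
  }
  if (exclude_border) {
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                           lab[, ncol(lab)]))
    border_ids <- border_ids[border_ids > 0]
    if (length(border_ids)) lab[lab %in% border_ids] <- 0L
  }
  relabel(lab)
}

#' Tabulate segmented cells
#'
#' Builds the per-cell record table from matched cell and nucleus label maps:
#' centroids of each cell mask and of the nucleus it contains.
#'
#' @param cell_labels Integer cell label matrix.
#' @param nucleus_labels Integer nucleus label matrix (same seeds).
#' @param treatment Optional treatment label recycled across cells.
#' @return A tibble: `cell_id`, `x_px`, `y_px` (cell-mask centroid),
#'   `nuc_x_px`, `nuc_y_px`, `area_px`, `treatment`.
#' @export
cell_table <- function(cell_labels, nucleus_labels = NULL, treatment = NA_character_) {
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  if (length(ids) == 0)
    return(tibble::tibble(cell_id = integer(), x_px = numeric(),
                          y_px = numeric(), nuc_x_px = numeric(),
                          nuc_y_px = numeric(), area_px = numeric(),
                          treatment = character()))
  cen <- label_centroids(cell_labels, ids)
  out <- tibble::tibble(cell_id = ids, x_px = cen[, 1], y_px = cen[, 2],
                        area_px = cen[, 3],
                        nuc_x_px = NA_real_, nuc_y_px = NA_real_,
                        treatment = treatment)
  if (!is.null(nucleus_labels)) {
    for (i in seq_along(ids)) {
      # nucleus inside this cell: majority nucleus label within the mask
      nl <- nucleus_labels[cell_labels == ids[i]]
      nl <- nl[nl > 0]
      if (length(nl)) {
        nid <- as.integer(names(which.max(table(nl))))
        ncen <- label_centroids(nucleus_labels, nid)
        out$nuc_x_px[i] <- ncen[1, 1]; out$nuc_y_px[i] <- ncen[1, 2]
      }
    }
  }
  dplyr::relocate(out, "cell_id", "x_px", "y_px", "nuc_x_px", "nuc_y_px",
                  "area_px", "treatment")
}

label_centroids <- function(lab, ids) {
  nz <- which(lab > 0, arr.ind = TRUE)
  vals <- lab[lab > 0]
  t(vapply(ids, function(id) {
    sel <- vals == id
    c(mean(nz[sel, 1]), mean(nz[sel, 2]), sum(sel))
  }, numeric(3)))
}

#' Detect intracellular fragments per cell
#'
#' Within each cell mask, thresholds the marker channel at a per-cell robust
#' cutoff (median + `k` * MAD of the cell's pixels), labels 4-connected
#' components, filters by size, and returns per-fragment centroids, areas and
#' integrated intensities. Raising `k` can only shrink the foreground, so the
#' fragment count is non-increasing in `k`.
#'
#' @param cell_labels Integer cell label matrix (or a `scene_bundle`'s truth
#'   labels, for the ground-truth bypass).
#' @param marker_channel 2D numeric matrix, same shape as the label map.
#' @param min_area_px Minimum fragment area kept (default 4 px).
#' @param k MAD multiplier of the robust threshold (default 3).
#' @return A tibble with one row per fragment: `cell_id`, `fragment_id`,
#'   `x_px`, `y_px` (intensity-weighted centroid), `area_px`, `intensity`
#'   (integrated). Cells with no fragment simply contribute no rows.
#' @export
detect_fragments <- function(cell_labels, marker_channel, min_area_px = 4,
                             k = 3) {
  stopifnot(is.matrix(cell_labels), is.matrix(marker_channel),
            all(dim(cell_labels) == dim(marker_channel)))
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- cell_labels == ids[i]
    vals <- marker_channel[sel]
    med <- stats::median(vals)
    # the range floor keeps a zero-MAD (noise-free) cell from thresholding
    # inside the PSF tails, which would fuse neighbouring fragments
    thr <- med + max(k * stats::mad(vals), 0.1 * (max(vals) - med))
    mask <- sel & marker_channel > thr
    if (!any(mask)) next
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(
      EBImage::Image(mask * 1))))
    storage.mode(lab) <- "integer"
    lab <- filter_small_labels(lab, min_area_px)
    if (max(lab) == 0) next
    fids <- seq_len(max(lab))
    rows <- lapply(fids, function(fid) {
      px <- which(lab == fid, arr.ind = TRUE)
      raw <- marker_channel[px]
      w <- raw - med # background-corrected weights give sub-pixel centroids
      tibble::tibble(cell_id = ids[i], fragment_id = fid,
                     x_px = sum(px[, 1] * w) / sum(w),
                     y_px = sum(px[, 2] * w) / sum(w),
                     area_px = nrow(px), intensity = sum(raw))
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(cell_id = integer(), fragment_id = integer(),
                          x_px = numeric(), y_px = numeric(),
                          area_px = numeric(), intensity = numeric())
  res
}
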