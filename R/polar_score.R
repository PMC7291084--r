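#' Polar distribution score of organelle fragments
#'
#' The polar distribution score (PDS) quantifies how anisotropically organelle
#' fragments are arranged around a cell centre. Fragment centroids are
#' converted to polar coordinates about the centre, rotated so their circular
#' mean angle is zero, binned into eight equal angular sectors, and the score
#' is the sum over sectors of the absolute deviation of each sector's
#' frequency from the uniform value 1/8. A score of 0 means fragments ring the
#' centre uniformly (fully dispersed); the maximum of 1.75 means all fragments
#' fall in a single sector (fully compacted, e.g. an intact juxtanuclear
#' Golgi). Fragment radii are ignored: the score is purely angular, and each
#' fragment counts once regardless of its size or brightness.
#'
#' @name polar_score
NULL

# wrap into (-pi, pi]
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Convert fragment centroids to polar angles about a centre
#'
#' Returns `atan2(y - cy, x - cx)` for each fragment, in `(-pi, pi]`. The
#' radius is discarded: downstream scoring uses angles only. A fragment lying
#' exactly at the centre has no defined angle and is dropped with a warning.
#'
#' @param x,y Numeric vectors of fragment centroid coordinates (pixels).
#' @param center Length-2 numeric `(cx, cy)`.
#' @return Numeric vector of angles in radians.
#' @export
fragment_angles <- function(x, y, center) {
  stopifnot(length(x) == length(y), length(center) == 2)
  if (length(x) < 1) stop("need at least one fragment", call. = FALSE)
  dx <- x - center[1]; dy <- y - center[2]
  at_centre <- dx == 0 & dy == 0
  if (any(at_centre)) {
    warning(sum(at_centre), " fragment(s) exactly at the centre dropped ",
            "(undefined angle)", call. = FALSE)
    dx <- dx[!at_centre]; dy <- dy[!at_centre]
  }
  wrap_angle(atan2(dy, dx))
}

#' Circular mean of a set of angles
#'
#' The direction of the resultant vector of unit vectors at the given angles:
#' `atan2(mean(sin), mean(cos))`. When the resultant length is (near) zero —
#' e.g. two antipodal angles — the mean direction is undefined; by convention
#' 0 is returned and the result is flagged degenerate.
#'
#' @param angles Numeric vector of angles in radians (>= 1).
#' @param tol Resultant length below which the mean is declared degenerate.
#' @return A list with `mean` (radians), `resultant_length` in `[0, 1]`, and
#'   logical `degenerate`.
#' @export
circular_mean <- function(angles, tol = 1e-8) {
  if (length(angles) < 1) stop("need at least one angle", call. = FALSE)
  s <- mean(sin(angles)); c <- mean(cos(angles))
  r <- sqrt(s^2 + c^2)
  if (r < tol) {
    list(mean = 0, resultant_length = r, degenerate = TRUE)
  } else {
    list(mean = atan2(s, c), resultant_length = r, degenerate = FALSE)
  }
}

#' Rotate angles to a zero mean angle
#'
#' Subtracts the circular mean direction from every angle and wraps the result
#' back into `(-pi, pi]`, so the rotated set has circular mean 0 (for
#' non-degenerate input).
#'
#' @param angles Numeric vector of angles in radians.
#' @param mean_angle The circular mean to subtract (radians).
#' @return Numeric vector of normalized angles in `(-pi, pi]`.
#' @export
normalize_angles <- function(angles, mean_angle) {
  wrap_angle(angles - mean_angle)
}

#' Angular histogram over equal sectors
#'
#' Bins angles into `n_bins` equal half-open sectors `[edge_k, edge_{k+1})`
#' covering `(-pi, pi]`, with edges at `-pi + k * 2 * pi / n_bins`. An angle
#' falling exactly on an interior edge is assigned to the upper bin.
#'
#' @param angles Numeric vector of angles in `(-pi, pi]` (>= 1).
#' @param n_bins Number of sectors (>= 2; default 8).
#' @return An object of class `polar_histogram`: list with `counts`,
#'   `frequencies` (summing to 1), `bin_edges` (length `n_bins + 1`), and
#'   `n_bins`.
#' @export
polar_histogram <- function(angles, n_bins = 8) {
  stopifnot(n_bins >= 2)
  if (length(angles) < 1) stop("need at least one angle", call. = FALSE)
  angles <- wrap_angle(angles)
  edges <- -pi + (0:n_bins) * 2 * pi / n_bins
  # half-open [lo, hi): index by floor; angle == pi (top edge) wraps to bin 1,
  # consistent with wrapping pi - eps' antipode -pi into the first sector
  idx <- floor((angles + pi) / (2 * pi / n_bins)) + 1L
  idx[idx > n_bins] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = counts, frequencies = counts / sum(counts),
                 bin_edges = edges, n_bins = as.integer(n_bins)),
            class = "polar_histogram")
}

#' @export
print.polar_histogram <- function(x, ...) {
  cat("<polar_histogram>", x$n_bins, "bins, n =", sum(x$counts), "\n")
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Polar distribution score from an angular histogram
#'
#' `sum(|f_k - 1/n_bins|)` over sector frequencies `f_k`; bounded by
#' `[0, 2 * (1 - 1/n_bins)]`, i.e. `[0, 1.75]` for the standard 8 sectors.
#'
#' @param hist A [polar_histogram()], or a bare numeric vector of frequencies
#'   summing to 1.
#' @return The score (scalar).
#' @export
polar_distribution_score <- function(hist) {
  freqs <- if (inherits(hist, "polar_histogram")) {
    if (sum(hist$counts) == 0)
      stop("histogram built from 0 fragments: score undefined", call. = FALSE)
    hist$frequencies
  } else {
    stopifnot(is.numeric(hist), length(hist) >= 2)
    if (sum(hist) == 0)
      stop("all-zero frequency vector: score undefined", call. = FALSE)
    hist
  }
  sum(abs(freqs - 1 / length(freqs)))
}

#' Per-cell polar distribution score
#'
#' Chains the full scoring pipeline for one cell: fragment angles about the
#' centre, circular mean, zero-mean rotation, equal-sector histogram, score.
#'
#' @param fragments A data frame with fragment centroid columns `x_px`,
#'   `y_px` (one row per fragment).
#' @param center Length-2 numeric cell centre `(cx, cy)` in pixels.
#' @param n_bins Number of angular sectors (default 8).
#' @return A one-row tibble: `n_fragments`, `mean_angle`,
#'   `resultant_length`, `degenerate`, `pds`.
#' @export
pds_for_cell <- function(fragments, center, n_bins = 8) {
  if (is.null(fragments) || nrow(fragments) < 1)
    stop("cell has no fragments: excluded from scoring", call. = FALSE)
  ang <- fragment_angles(fragments$x_px, fragments$y_px, center)
  cm <- circular_mean(ang)
  norm <- normalize_angles(ang, cm$mean)
  h <- polar_histogram(norm, n_bins = n_bins)
  tibble::tibble(n_fragments = length(ang), mean_angle = cm$mean,
                 resultant_length = cm$resultant_length,
                 degenerate = cm$degenerate,
                 pds = polar_distribution_score(h))
}

#' Score every cell of a scene or fragment table
#'
#' Applies [pds_for_cell()] to each cell of a per-fragment table. Cells with
#' zero fragments are skipped (with a message); degenerate circular means are
#' flagged but, by default, kept in the output.
#'
#' @param fragments Per-fragment data frame with columns `cell_id`, `x_px`,
#'   `y_px`.
#' @param cells Per-cell data frame with columns `cell_id` and the centre
#'   coordinates. Which centre is used is set by `center`.
#' @param center `"cell"` (default) uses columns `x_px`/`y_px` of `cells`
#'   (the cell-mask centroid); `"nucleus"` uses `nuc_x_px`/`nuc_y_px`.
#' @param n_bins Number of angular sectors (default 8).
#' @return A tibble with one row per scored cell: `cell_id`, `n_fragments`,
#'   `mean_angle`, `resultant_length`, `degenerate`, `pds` (plus a
#'   `treatment` column if `cells` has one).
#' @export
pds_by_cell <- function(fragments, cells, center = c("cell", "nucleus"),
                        n_bins = 8) {
  center <- match.arg(center)
  cx_col <- if (center == "cell") "x_px" else "nuc_x_px"
  cy_col <- if (center == "cell") "y_px" else "nuc_y_px"
  stopifnot(all(c(cx_col, cy_col, "cell_id") %in% names(cells)),
            all(c("cell_id", "x_px", "y_px") %in% names(fragments)))
  empty <- setdiff(cells$cell_id, fragments$cell_id)
  if (length(empty) > 0)
    message(length(empty), " cell(s) with zero fragments skipped: ",
            paste(empty, collapse = ", "))
  scored <- dplyr::group_by(fragments, .data$cell_id)
  scored <- dplyr::group_modify(scored, function(df, key) {
    row <- dplyr::filter(cells, .data$cell_id == key$cell_id)
    pds_for_cell(df, c(row[[cx_col]][1], row[[cy_col]][1]), n_bins = n_bins)
  })
  scored <- dplyr::ungroup(scored)
  if ("treatment" %in% names(cells))
    scored <- dplyr::left_join(
      scored, dplyr::select(cells, "cell_id", "treatment"), by = "cell_id")
  scored
}

#' Normalize per-treatment mean scores to the negative control
#'
#' Computes the mean PDS per treatment and divides by the negative-control
#' mean. Normalized values below 1 read as "dispersed" relative to control;
#' values above 1 as "compacted".
#'
#' @param cell_scores Per-cell tibble from [pds_by_cell()], with a
#'   `treatment` column.
#' @param control Treatment label of the negative control (default `"NEG"`).
#' @return A tibble: `treatment`, `n_cells`, `mean_pds`, `normalized_pds`.
#' @export
normalize_pds <- function(cell_scores, control = "NEG") {
  stopifnot(all(c("treatment", "pds") %in% names(cell_scores)))
  if (!control %in% cell_scores$treatment)
    stop("control treatment '", control, "' absent", call. = FALSE)
  by_trt <- dplyr::summarise(
    dplyr::group_by(cell_scores, .data$treatment),
    n_cells = dplyr::n(), mean_pds = mean(.data$pds), .groups = "drop")
  ctrl <- by_trt$mean_pds[by_trt$treatment == control]
  if (ctrl <= 0)
    stop("control mean PDS is not positive; cannot normalize", call. = FALSE)
  dplyr::mutate(by_trt, normalized_pds = .data$mean_pds / ctrl)
}
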