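#' Image calibration
#'
#' Physical calibration of an image or time-lapse stack: the pixel size in
#' micrometres per pixel and, for time-lapse data, the interval between
#' consecutive frames in seconds. Both must be strictly positive and the pixel
#' size is assumed constant across all channels of a scene.
#'
#' @param pixel_size Micrometres per pixel (scalar > 0). The default of 0.1
#'   µm/px makes a 2 µm tubule span 20 pixels, comfortably resolvable.
#' @param frame_interval Seconds per frame for time-lapse stacks (scalar > 0).
#'   At the default 1 s, a one-minute video is 60 frames.
#' @return An object of class `image_calibration`: a list with elements
#'   `pixel_size` and `frame_interval`.
#' @examples
#' cal <- image_calibration()
#' cal$pixel_size
#' @export
image_calibration <- function(pixel_size = 0.1, frame_interval = 1) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1, pixel_size > 0,
            is.numeric(frame_interval), length(frame_interval) == 1,
            frame_interval > 0)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval),
            class = "image_calibration")
}

#' @export
print.image_calibration <- function(x, ...) {
  cat("<image_calibration> pixel_size =", x$pixel_size,
      "um/px, frame_interval =", x$frame_interval, "s\n")
  invisible(x)
}

um_to_px <- function(um, calibration) um / calibration$pixel_size
px_to_um <- function(px, calibration) px * calibration$pixel_size

as_calibration <- function(x) {
  if (inherits(x, "image_calibration")) return(x)
  if (is.list(x) && all(c("pixel_size", "frame_interval") %in% names(x)))
    return(image_calibration(x$pixel_size, x$frame_interval))
  stop("not an image_calibration", call. = FALSE)
}
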