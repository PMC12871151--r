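#' Timed, calibrated single-channel frame sequence
#'
#' An `image_stack` holds an ordered list of 2-D intensity matrices together
#' with the spatial and temporal calibration needed downstream: pixel size in
#' micrometres and the frame-to-frame interval in seconds.
#'
#' Coordinate convention used throughout the package: 0-based, origin at the
#' center of the pixel with index `[1, 1]`, `x` is the column index and `y`
#' the row index. All sub-pixel positions reported by detection and tracking
#' follow this convention.
#'
#' @param frames list of numeric matrices, all of identical dimension.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param frame_interval frame-to-frame interval in seconds (> 0).
#' @param channel_label free-text channel name (e.g. `"paxillin"`, `"gfp"`).
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval = 20,
                        channel_label = "") {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1 && any(dims != dims[, 1]))
    stop("all frames must have identical dimensions")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, channel_label = channel_label),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "image_stack '%s': %d frame(s) of %d x %d px, %.4g um/px, dt = %g s\n",
    x$channel_label, length(x$frames), d[1], d[2], x$pixel_size,
    x$frame_interval))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Number of frames and frame times of a stack
#'
#' @param stack an `image_stack`.
#' @return `frame_times()` returns the acquisition time of each frame in
#'   seconds, starting at 0.
#' @export
frame_times <- function(stack) {
  (seq_along(stack$frames) - 1) * stack$frame_interval
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Intensities are clipped to `[0, 65535]` and stored as unsigned 16-bit.
#' Calibration is not stored in the file; keep it in the run configuration.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  imgs <- lapply(stack$frames, function(f) {
    f <- pmin(pmax(round(f), 0), 65535)
    f / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval,channel_label calibration to attach; the
#'   TIFF itself carries none.
#' @return An `image_stack` with intensities rescaled back to 16-bit counts.
#' @export
read_stack_tiff <- function(path, pixel_size, frame_interval = 20,
                            channel_label = "") {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE),
                   error = function(e)
                     stop("failed to read TIFF '", path, "': ",
                          conditionMessage(e)))
  if (!is.list(imgs)) imgs <- list(imgs)
  frames <- lapply(imgs, function(im) {
    if (length(dim(im)) == 3) im <- im[, , 1]
    im * 65535
  })
  image_stack(frames, pixel_size, frame_interval, channel_label)
}
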