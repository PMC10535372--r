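#' RGB frame container
#'
#' A thin wrapper around an `H x W x 3` integer array of 8-bit RGB values.
#' Coordinates follow the endoscopy-image convention: `(0, 0)` is the
#' top-left pixel, `x` indexes columns and `y` rows.
#'
#' @param pixels an `H x W x 3` numeric array with values in `[0, 255]`, or
#'   in `[0, 1]` (autoscaled, as returned by [png::readPNG()]).
#' @param index 1-based frame ordinal used in reports.
#' @return an object of class `rgb_frame`.
#' @export
rgb_frame <- function(pixels, index = 1L) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] < 3) {
    abort("`pixels` must be an H x W x 3 array.", class = "airway_invalid_parameter")
  }
  pixels <- pixels[, , 1:3, drop = FALSE]
  if (max(pixels) <= 1 && min(pixels) >= 0 && !all(pixels == floor(pixels))) {
    pixels <- pixels * 255
  }
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("Pixel values must lie in [0, 255].", class = "airway_invalid_parameter")
  }
  structure(
    list(pixels = pixels, index = as.integer(index),
         width = dim(pixels)[2], height = dim(pixels)[1]),
    class = "rgb_frame"
  )
}

#' @export
print.rgb_frame <- function(x, ...) {
  cat(sprintf("<rgb_frame #%d: %d x %d>\n", x$index, x$width, x$height))
  invisible(x)
}

#' Read a frame sequence from a directory of PNG images
#'
#' Files are ordered by the numeric part of their filename (zero-padded or
#' not); the resulting frame indices are 1-based in file order.
#'
#' @param dir directory containing `.png` frames.
#' @return a list of [rgb_frame()] objects.
#' @export
read_frames <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0) {
    abort(sprintf("No PNG frames found in '%s'.", dir), class = "airway_io_error")
  }
  num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  ord <- order(ifelse(is.na(num), Inf, num), basename(files))
  files <- files[ord]
  lapply(seq_along(files), function(i) {
    rgb_frame(png::readPNG(files[i]), index = i)
  })
}

#' Write a frame sequence as numbered PNG images
#'
#' @param frames list of [rgb_frame()] objects.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(frames, function(f) {
    path <- file.path(dir, sprintf("frame_%05d.png", f$index))
    png::writePNG(f$pixels / 255, path)
    path
  }, character(1))
  invisible(paths)
}
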