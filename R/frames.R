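#' Construct a video frame
#'
#' A frame is a plain numeric array of dimension `H x W x 3` holding 8-bit
#' scale intensities (values in `[0, 255]`), with the acquisition time in
#' seconds and the frame index carried as attributes.
#'
#' @param pixels Numeric array `H x W x 3` with values in `[0, 255]`.
#' @param t Acquisition time in seconds from the start of the recording.
#' @param index 1-based frame number.
#' @return The validated array with attributes `t` and `index`.
#' @export
new_frame <- function(pixels, t = 0, index = 1L) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array.")
  }
  if (d[1] < 1L || d[2] < 1L) abort("frame must have positive height and width.")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    abort("frame intensities must lie in [0, 255].")
  }
  attr(pixels, "t") <- t
  attr(pixels, "index") <- as.integer(index)
  pixels
}

#' Frame luma (grayscale) image
#'
#' BT.601 luma weights (0.299, 0.587, 0.114), the convention used throughout
#' the package for sharpness statistics.
#'
#' @param frame `H x W x 3` numeric array.
#' @return `H x W` numeric matrix.
#' @export
frame_gray <- function(frame) {
  d <- dim(frame)
  .rgb_gray(frame, d[1], d[2])
}

#' Frame sources
#'
#' A frame source is a lazy stream of frames: rendering a ten-minute session
#' at 25 Hz would not fit in memory as one object, so consumers pull frames
#' one at a time with `get_frame(i)`. Sources carry per-frame metadata
#' (time, ground-truth face box, whether the renderer blurred the frame) in a
#' tibble, which lets unit tests bypass face detection deterministically.
#'
#' @param n_frames Number of frames.
#' @param fps Frame rate in Hz.
#' @param width,height Frame dimensions in pixels.
#' @param get_frame Function of a single index returning the frame array.
#' @param meta Tibble with one row per frame: columns `index`, `t`,
#'   `blurred`, `box_x`, `box_y`, `box_w`, `box_h` (0-based, half-open).
#' @return An object of class `frame_source`.
#' @export
frame_source <- function(n_frames, fps, width, height, get_frame, meta) {
  structure(
    list(n_frames = as.integer(n_frames), fps = fps,
         width = as.integer(width), height = as.integer(height),
         get_frame = get_frame, meta = meta),
    class = "frame_source"
  )
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source: %d frames, %g Hz, %dx%d>\n",
              x$n_frames, x$fps, x$height, x$width))
  invisible(x)
}

#' Read a directory of numbered PNG frames as a frame source
#'
#' Expects files written by [simulate_session()] (`frame_000001.png`, ...)
#' plus an optional `frames.csv` metadata table alongside; without metadata
#' the source has no ground-truth boxes and face detection must be used.
#'
#' @param dir Directory containing the PNG frames.
#' @param fps Frame rate in Hz (default 25).
#' @return A [frame_source()].
#' @export
frame_source_from_dir <- function(dir, fps = 25) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0L) abort(sprintf("no frame_*.png files found in '%s'.", dir))
  first <- png_to_frame(files[1])
  d <- dim(first)
  meta_path <- file.path(dir, "frames.csv")
  if (file.exists(meta_path)) {
    meta <- tibble::as_tibble(read.csv(meta_path))
  } else {
    n <- length(files)
    meta <- tibble(index = seq_len(n), t = (seq_len(n) - 1) / fps,
                   blurred = NA, box_x = NA_real_, box_y = NA_real_,
                   box_w = NA_real_, box_h = NA_real_)
  }
  frame_source(
    n_frames = length(files), fps = fps, width = d[2], height = d[1],
    get_frame = function(i) {
      fr <- png_to_frame(files[i])
      new_frame(fr, t = (i - 1) / fps, index = i)
    },
    meta = meta
  )
}

# PNG <-> frame array helpers (png stores [0,1], row-major top-down like us)
png_to_frame <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  px[, , 1:3, drop = FALSE] * 255
}

frame_to_png <- function(frame, path) {
  png::writePNG(pmin(pmax(frame / 255, 0), 1), target = path)
}
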