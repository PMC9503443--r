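#' Face bounding box
#'
#' 0-based, half-open pixel box: columns `x .. x + w - 1`, rows
#' `y .. y + h - 1` in 0-based coordinates.
#'
#' @param x,y Top-left corner (0-based pixels).
#' @param w,h Width and height in pixels (> 0).
#' @param source `"detected"` or `"ground_truth"`.
#' @return A `face_box` list.
#' @export
face_box <- function(x, y, w, h, source = c("detected", "ground_truth")) {
  source <- match.arg(source)
  if (w <= 0 || h <= 0) abort("face box must have positive width and height.")
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h), source = source),
            class = "face_box")
}

#' Intersection-over-union of two boxes
#'
#' @param a,b [face_box()] objects.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Locate the face in a frame
#'
#' A deterministic skin-chromaticity detector suited to frontal faces on
#' non-skin backgrounds: pixels matching the classic RGB skin rule
#' (R > 95, G > 40, B > 20, R > G, R > B, max - min > 15) are collected,
#' the box spanning the central 96% of their row and column marginals is
#' taken (trimming stray matches), and the detection is accepted only when
#' enough skin pixels fill the box. When the frame carries a ground-truth
#' box (synthetic frames do, in the source metadata), pass it via
#' `ground_truth` to bypass detection deterministically.
#'
#' @param frame `H x W x 3` numeric array.
#' @param min_size Minimum acceptable box side in pixels.
#' @param min_fill Minimum fraction of box pixels that must be skin.
#' @param ground_truth Optional [face_box()] to return verbatim (with
#'   `source = "ground_truth"`).
#' @return A [face_box()].
#' @export
detect_face <- function(frame, min_size = 40, min_fill = 0.3,
                        ground_truth = NULL) {
  if (!is.null(ground_truth)) {
    gb <- ground_truth
    return(face_box(gb$x, gb$y, gb$w, gb$h, source = "ground_truth"))
  }
  d <- dim(frame)
  if (is.null(d) || length(d) != 3L) abort("`frame` must be H x W x 3.")
  m <- .skin_marginals(frame, d[1], d[2])
  total <- m$total
  idx <- attr(frame, "index") %||% NA_integer_
  fail <- function() {
    abort(sprintf("no face detected in frame %s.", idx),
          class = "facehr_no_face", frame_index = idx)
  }
  if (total < min_size^2) fail()
  q <- function(counts, lo, hi) {
    cs <- cumsum(counts)
    c(which(cs >= lo * total)[1], which(cs >= hi * total)[1])
  }
  ry <- q(m$rows, 0.02, 0.98)
  rx <- q(m$cols, 0.02, 0.98)
  w <- rx[2] - rx[1] + 1L; h <- ry[2] - ry[1] + 1L
  if (w < min_size || h < min_size) fail()
  # marginal trimming keeps >= 96% of matches; fill is assessed on the box
  fill <- 0.96 * total / (as.numeric(w) * h)
  if (fill < min_fill) fail()
  face_box(rx[1] - 1L, ry[1] - 1L, w, h, source = "detected")
}

#' Crop a face box and resize to a square crop
#'
#' Bilinear resize of the box contents to `size x size` (default 400),
#' regardless of the box aspect ratio. A box already at the target size is
#' returned exactly (identity resize).
#'
#' @param frame `H x W x 3` numeric array.
#' @param box [face_box()], fully inside the frame.
#' @param size Output side length in pixels.
#' @return `size x size x 3` numeric array.
#' @export
crop_resize_face <- function(frame, box, size = 400) {
  d <- dim(frame)
  if (box$x < 0 || box$y < 0 || box$x + box$w > d[2] || box$y + box$h > d[1]) {
    abort("face box lies outside the frame.")
  }
  .bilinear_resize(frame, d[1], d[2], d[3],
                   box$x, box$y, box$w, box$h, size, size)
}

#' Forehead patch specification
#'
#' Patch-centre position as fractions of the square face crop, plus the
#' patch side length. The default places a 16 x 16 patch on the lower
#' forehead of a frontal 400 x 400 crop (centre at 50% width, 18% height —
#' just above typical brow position).
#'
#' @param cx_frac,cy_frac Patch centre as fractions of the crop side.
#' @param size Patch side length in pixels (>= 1).
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(cx_frac = 0.5, cy_frac = 0.18, size = 16) {
  if (size < 1) abort("patch `size` must be >= 1.")
  structure(list(cx_frac = cx_frac, cy_frac = cy_frac, size = as.integer(size)),
            class = "patch_spec")
}

#' Extract the forehead patch from a face crop
#'
#' Axis-aligned `size x size` crop centred at
#' `(floor(cx_frac * side), floor(cy_frac * side))` in 0-based coordinates.
#'
#' @param face Square face crop (`side x side x 3` array).
#' @param spec [patch_spec()].
#' @return `size x size x 3` numeric array.
#' @export
extract_forehead_patch <- function(face, spec = patch_spec()) {
  d <- dim(face)
  side_h <- d[1]; side_w <- d[2]
  cx <- floor(spec$cx_frac * side_w)
  cy <- floor(spec$cy_frac * side_h)
  x0 <- cx - spec$size %/% 2L
  y0 <- cy - spec$size %/% 2L
  if (x0 < 0 || y0 < 0 || x0 + spec$size > side_w || y0 + spec$size > side_h) {
    abort("forehead patch exceeds the crop bounds.")
  }
  face[y0 + seq_len(spec$size), x0 + seq_len(spec$size), , drop = FALSE]
}
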