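#' Color models tracked by the pipeline
#' @export
COLOR_MODELS <- c("RGB", "HSV", "YCbCr", "Lab", "YUV")

#' Channel names of a color model
#'
#' @param model One of `r paste(COLOR_MODELS, collapse = ", ")`.
#' @return Character vector of three channel names.
#' @export
model_channels <- function(model) {
  switch(match.arg(model, COLOR_MODELS),
         RGB = c("R", "G", "B"),
         HSV = c("H", "S", "V"),
         YCbCr = c("Y", "Cb", "Cr"),
         Lab = c("L", "a", "b"),
         YUV = c("Y", "U", "V"))
}

#' Chromaticity normalization
#'
#' Divides each pixel's components by their sum, so per-pixel components are
#' nonnegative and sum to exactly 1. This removes brightness (any
#' multiplicative illumination change, such as mains-frequency lamp flicker)
#' and leaves only relative color. Pure black pixels, whose component sum is
#' zero, are assigned the achromatic sentinel (1/3, 1/3, 1/3), which keeps
#' the unit-sum identity.
#'
#' @param image `H x W x 3` numeric array on the 8-bit scale.
#' @return `H x W x 3` array of chromaticities; each pixel sums to 1.
#' @export
normalize_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) abort("`image` must be H x W x 3.")
  s <- image[, , 1] + image[, , 2] + image[, , 3]
  zero <- s == 0
  s[zero] <- 1
  out <- image / as.numeric(s)
  if (any(zero)) {
    idx <- which(zero)
    plane <- d[1] * d[2]
    out[idx] <- 1 / 3
    out[idx + plane] <- 1 / 3
    out[idx + 2 * plane] <- 1 / 3
  }
  out
}

#' Convert a chromaticity-normalized image to a target color model
#'
#' The normalized chromaticity (per-pixel sum 1) is first rescaled by 255 so
#' conversions operate on their native 8-bit domain, then converted using
#' pinned standards: HSV by the hexcone model (H in degrees `[0, 360)`, S in
#' `[0, 1]`, V on the 8-bit scale); YCbCr per BT.601 with the 8-bit chroma
#' offset of 128; YUV per BT.601 analog weights (U, V centred on 0); Lab via
#' sRGB with D65 white (L in `[0, 100]`). `model = "RGB"` passes the
#' rescaled chromaticity through unchanged. Achromatic pixels map to the
#' achromatic locus of every model (S = 0, Cb = Cr = 128, a = b = 0,
#' U = V = 0).
#'
#' @param norm `H x W x 3` chromaticity array from [normalize_rgb()].
#' @param model One of `r paste(COLOR_MODELS, collapse = ", ")`.
#' @return `H x W x 3` array; channel order given by [model_channels()].
#' @export
convert_color <- function(norm, model) {
  if (!is.character(model) || length(model) != 1L || !(model %in% COLOR_MODELS)) {
    abort(sprintf("unknown color model '%s'; expected one of %s.",
                  paste(model, collapse = ","), paste(COLOR_MODELS, collapse = ", ")))
  }
  d <- dim(norm)
  if (length(d) != 3L || d[3] != 3L) abort("`norm` must be H x W x 3.")
  rgb255 <- norm * 255
  R <- rgb255[, , 1]; G <- rgb255[, , 2]; B <- rgb255[, , 3]
  out <- switch(
    model,
    RGB = rgb255,
    HSV = {
      m <- grDevices::rgb2hsv(rbind(as.numeric(R), as.numeric(G), as.numeric(B)),
                              maxColorValue = 255)
      array(c(m[1, ] * 360, m[2, ], m[3, ] * 255), dim = d)
    },
    YCbCr = {
      Y <- 0.299 * R + 0.587 * G + 0.114 * B
      Cb <- 128 - 0.168736 * R - 0.331264 * G + 0.5 * B
      Cr <- 128 + 0.5 * R - 0.418688 * G - 0.081312 * B
      array(c(Y, Cb, Cr), dim = d)
    },
    YUV = {
      Y <- 0.299 * R + 0.587 * G + 0.114 * B
      array(c(Y, 0.492 * (B - Y), 0.877 * (R - Y)), dim = d)
    },
    Lab = {
      m <- grDevices::convertColor(cbind(as.numeric(R), as.numeric(G),
                                         as.numeric(B)) / 255,
                                   from = "sRGB", to = "Lab")
      array(as.numeric(m), dim = d)
    })
  dimnames(out) <- list(NULL, NULL, model_channels(model))
  out
}

#' Spatial mean of a patch channel
#'
#' The arithmetic mean over all `M x N` patch pixels of one channel — the
#' operation that turns a forehead patch into one time sample per channel.
#'
#' @param patch_channel Numeric matrix (or vector) of pixel values.
#' @return Scalar mean.
#' @export
patch_average <- function(patch_channel) {
  if (length(patch_channel) == 0L) abort("empty patch.")
  mean(patch_channel)
}

#' Combined luminance-weighted color intensity (percent)
#'
#' `I = 100 * (0.21 R + 0.72 G + 0.07 B) / 255`: a single percent-scale
#' summary of an RGB triple, with full-scale white mapping to 100.
#'
#' @param r,g,b Numeric scalars or vectors on the 8-bit scale.
#' @return Intensity in percent.
#' @export
combined_intensity <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 255)) abort("inputs must lie in [0, 255].")
  (0.21 * r + 0.72 * g + 0.07 * b) / 255 * 100
}
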