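#' Frame sharpness statistic
#'
#' Variance of the 4-neighbour Laplacian of the luma image (`stat =
#' "laplacian"`, the standard blur metric) or the raw variance of luma
#' pixels (`stat = "pixel_variance"`). Motion blur attenuates high spatial
#' frequencies, so both statistics drop on blurred frames.
#'
#' @param frame `H x W x 3` numeric array.
#' @param stat Which statistic to compute.
#' @return Scalar sharpness in squared intensity units.
#' @export
frame_sharpness <- function(frame, stat = c("laplacian", "pixel_variance")) {
  stat <- match.arg(stat)
  g <- frame_gray(frame)
  if (stat == "laplacian") .laplacian_variance(g) else var(as.numeric(g))
}

#' Flag a blurred frame
#'
#' A frame is blurred when its sharpness statistic falls below `threshold`.
#'
#' @inheritParams frame_sharpness
#' @param threshold Positive sharpness threshold (variance units; default
#'   100 on the 8-bit scale).
#' @return Logical.
#' @export
is_blurred <- function(frame, threshold = 100,
                       stat = c("laplacian", "pixel_variance")) {
  if (!is.numeric(threshold) || threshold <= 0) abort("`threshold` must be > 0.")
  frame_sharpness(frame, stat) < threshold
}

#' Linear-motion point-spread function
#'
#' A normalized 1-pixel-wide line of the given length and angle, the PSF of
#' uniform linear motion during exposure (head bob while cycling is
#' predominantly horizontal in a frontal view, hence the default angle 0).
#'
#' @param length Blur extent in pixels (odd lengths keep the PSF centred).
#' @param angle Motion direction in degrees (0 = horizontal).
#' @return Matrix summing to 1.
#' @export
motion_kernel <- function(length = 9, angle = 0) {
  length <- as.integer(length)
  if (length < 1L) abort("`length` must be >= 1.")
  if (length == 1L) return(matrix(1, 1, 1))
  half <- (length - 1) / 2
  th <- angle * pi / 180
  tpos <- seq(-half, half, by = 1)
  xs <- round(tpos * cos(th)) ; ys <- round(tpos * sin(th))
  k <- matrix(0, max(ys) - min(ys) + 1L, max(xs) - min(xs) + 1L)
  for (i in seq_along(tpos)) {
    k[ys[i] - min(ys) + 1L, xs[i] - min(xs) + 1L] <-
      k[ys[i] - min(ys) + 1L, xs[i] - min(xs) + 1L] + 1
  }
  k / sum(k)
}

#' Convolve a frame with a PSF (reflective borders)
#'
#' Direct spatial convolution, used by the synthetic renderer to motion-blur
#' frames and by tests as the forward model for deconvolution.
#'
#' @param frame `H x W x 3` numeric array.
#' @param psf Convolution kernel (matrix summing to 1).
#' @return Blurred frame, same shape, clipped to `[0, 255]`.
#' @export
convolve_frame <- function(frame, psf) {
  d <- dim(frame)
  if (nrow(psf) > d[1] || ncol(psf) > d[2]) abort("`psf` larger than frame.")
  out <- frame
  for (c in 1:3) {
    ch <- frame[, , c]
    if (nrow(psf) == 1L) {
      out[, , c] <- .sep_conv2(ch, kx = rev(psf[1, ]), ky = 1)
    } else if (ncol(psf) == 1L) {
      out[, , c] <- .sep_conv2(ch, kx = 1, ky = rev(psf[, 1]))
    } else {
      out[, , c] <- conv2_direct(ch, psf)
    }
  }
  pmin(pmax(out, 0), 255)
}

# dense centred 2-D convolution with reflective padding (non-separable PSFs;
# kernels are small so the shift-accumulate loop is cheap)
conv2_direct <- function(ch, psf) {
  ph <- nrow(psf); pw <- ncol(psf)
  ry <- (ph - 1L) %/% 2L; rx <- (pw - 1L) %/% 2L
  H <- nrow(ch); W <- ncol(ch)
  my <- ph - 1L; mx <- pw - 1L
  if (my > H - 1L || mx > W - 1L) abort("`psf` larger than frame allows.")
  ridx <- c(rev(seq_len(my)) + 1L, seq_len(H), H - seq_len(my))
  cidx <- c(rev(seq_len(mx)) + 1L, seq_len(W), W - seq_len(mx))
  P <- ch[ridx, cidx, drop = FALSE]
  out <- matrix(0, H, W)
  for (a in seq_len(ph)) {
    u <- a - 1L - ry
    for (b in seq_len(pw)) {
      v <- b - 1L - rx
      w <- psf[a, b]
      if (w == 0) next
      out <- out + w * P[(seq_len(H)) + my - u, (seq_len(W)) + mx - v]
    }
  }
  out
}

#' Wiener deconvolution of a frame
#'
#' Frequency-domain Wiener restoration applied per channel: with `H` the
#' PSF's transfer function, each channel is filtered by
#' `conj(H) / (|H|^2 + nsr)`. `nsr` is the noise-to-signal power ratio;
#' `nsr = 0` gives the (unregularized) inverse filter, large `nsr`
#' attenuates everything.
#'
#' @param frame `H x W x 3` numeric array.
#' @param psf Nonnegative kernel summing to 1, no larger than the frame.
#' @param nsr Noise-to-signal power ratio, `>= 0` (default 0.01).
#' @return Restored frame, same shape, clipped to `[0, 255]`.
#' @export
wiener_deblur <- function(frame, psf = motion_kernel(9), nsr = 0.01) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L) abort("`frame` must be H x W x 3.")
  if (nrow(psf) > d[1] || ncol(psf) > d[2]) abort("`psf` larger than frame.")
  if (any(psf < 0) || abs(sum(psf) - 1) > 1e-8) abort("`psf` must be nonnegative and sum to 1.")
  if (nsr < 0) abort("`nsr` must be >= 0.")
  G <- wiener_transfer(d[1], d[2], psf, nsr)
  out <- frame
  for (c in 1:3) {
    out[, , c] <- Re(fft(fft(frame[, , c]) * G, inverse = TRUE)) / (d[1] * d[2])
  }
  pmin(pmax(out, 0), 255)
}

.wiener_cache <- new.env(parent = emptyenv())

# Wiener restoration filter conj(H)/(|H|^2 + nsr) for given frame size;
# cached, since extraction applies it to many identically sized frames
wiener_transfer <- function(H, W, psf, nsr) {
  key <- paste(H, W, nsr, paste(signif(psf, 10), collapse = ","), sep = "|")
  cached <- .wiener_cache[[key]]
  if (!is.null(cached)) return(cached)
  kp <- matrix(0, H, W)
  ph <- nrow(psf); pw <- ncol(psf)
  kp[seq_len(ph), seq_len(pw)] <- psf
  # centre the PSF at the origin so restoration introduces no shift
  cy <- (ph - 1L) %/% 2L; cx <- (pw - 1L) %/% 2L
  kp <- kp[((seq_len(H) - 1L + cy) %% H) + 1L, ((seq_len(W) - 1L + cx) %% W) + 1L]
  Hf <- fft(kp)
  G <- Conj(Hf) / (Mod(Hf)^2 + nsr)
  .wiener_cache[[key]] <- G
  G
}

#' Gaussian denoising of a frame
#'
#' Per-channel separable Gaussian convolution with reflective borders;
#' `sigma = 0` is the identity.
#'
#' @param frame `H x W x 3` numeric array.
#' @param sigma Gaussian standard deviation in pixels, `>= 0`.
#' @return Denoised frame, same shape.
#' @export
gaussian_denoise <- function(frame, sigma = 1) {
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (sigma == 0) return(frame)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(frame)
  out <- .sep_conv2_3(frame, d[1], d[2], kx = k, ky = k)
  attributes(out)$dim <- d
  attr(out, "t") <- attr(frame, "t")
  attr(out, "index") <- attr(frame, "index")
  out
}
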