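#' Synthetic exercise-session scenario
#'
#' Defines the ground truth for a rendered exercise recording: a participant
#' (age, starting heart rate), a submaximal ramp that terminates at 85% of
#' the age-predicted maximum `208 - 0.7 * age`, a linear coupling between
#' maxHR% and the forehead color, and the corruptions a real recording shows
#' (mains-lamp brightness flicker, motion blur on a fraction of frames,
#' additive noise). All randomness derives from `seed`, so identical
#' scenarios render identical sessions.
#'
#' @param age Participant age in years.
#' @param initial_hr Heart rate at exercise start, bpm; must be below the
#'   ramp ceiling `0.85 * (208 - 0.7 * age)`.
#' @param duration Session length in seconds.
#' @param frame_rate Video frame rate in Hz.
#' @param coupling Named length-3 vector: change in forehead patch color
#'   (8-bit intensity units) per maxHR% percentage point, per raw channel.
#' @param baseline_color Length-3 RGB vector, 8-bit scale, each in (0, 255):
#'   the forehead color extrapolated to maxHR% = 0.
#' @param noise_sd SD of the Gaussian noise added to the per-second
#'   ground-truth channel signals (8-bit intensity units).
#' @param flicker_amplitude Fractional amplitude of the multiplicative
#'   brightness flicker.
#' @param flicker_freq Frequency of the recorded flicker beat in Hz (the
#'   low-frequency beat between 100 Hz lamp intensity and the unsynchronised
#'   camera sampling).
#' @param blur_fraction Fraction of frames motion-blurred, in `[0, 1]`.
#' @param blur_length Length of the horizontal motion-blur kernel in pixels.
#' @param pixel_noise_sd SD of additive per-pixel sensor noise at render
#'   time (8-bit units; 0 disables it — patch-level variability is already
#'   carried by `noise_sd`).
#' @param width,height Rendered frame size in pixels (study-scale recordings
#'   are 1920 x 1080; the default is a reduced size practical for analysis
#'   at desk scale).
#' @param hr_jitter_ar,hr_jitter_sd AR(1) coefficient and innovation SD (bpm)
#'   of the beat-to-beat jitter added to the heart-rate ramp.
#' @param seed Integer seed; required, every random draw flows from it.
#' @return A validated `facehr_scenario` list.
#' @export
scenario <- function(age = 27, initial_hr = 97, duration = 600,
                     frame_rate = 25,
                     coupling = c(R = 0.25, G = -0.05, B = -0.05),
                     baseline_color = c(R = 200, G = 140, B = 110),
                     noise_sd = 1, flicker_amplitude = 0.02,
                     flicker_freq = 2.5, blur_fraction = 0.1,
                     blur_length = 9, pixel_noise_sd = 0,
                     width = 640, height = 360,
                     hr_jitter_ar = 0.9, hr_jitter_sd = 1,
                     seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: every synthetic session must be reproducible.")
  }
  if (duration <= 0) abort("`duration` must be > 0.")
  if (frame_rate <= 0) abort("`frame_rate` must be > 0.")
  if (blur_fraction < 0 || blur_fraction > 1) abort("`blur_fraction` must lie in [0, 1].")
  if (length(coupling) != 3L) abort("`coupling` must have 3 components.")
  if (length(baseline_color) != 3L || any(baseline_color <= 0) ||
      any(baseline_color >= 255)) {
    abort("`baseline_color` components must lie strictly inside (0, 255).")
  }
  structure(list(
    age = age, initial_hr = initial_hr, duration = as.integer(duration),
    frame_rate = frame_rate, coupling = setNames(as.numeric(coupling), c("R", "G", "B")),
    baseline_color = setNames(as.numeric(baseline_color), c("R", "G", "B")),
    noise_sd = noise_sd, flicker_amplitude = flicker_amplitude,
    flicker_freq = flicker_freq, blur_fraction = blur_fraction,
    blur_length = as.integer(blur_length), pixel_noise_sd = pixel_noise_sd,
    width = as.integer(width), height = as.integer(height),
    hr_jitter_ar = hr_jitter_ar, hr_jitter_sd = hr_jitter_sd,
    seed = as.integer(seed)
  ), class = "facehr_scenario")
}

#' Ramp ceiling of a scenario
#'
#' 85% of the age-predicted maximal heart rate `208 - 0.7 * age` — the
#' submaximal test-termination rule.
#'
#' @param age Age in years.
#' @return Ceiling in bpm.
#' @export
ramp_ceiling <- function(age) 0.85 * (208 - 0.7 * age)

#' Generate a ground-truth heart-rate ramp
#'
#' A monotone nondecreasing linear trend from `initial_hr` that saturates at
#' the ramp ceiling (reached at 90% of the session, then held), with seeded
#' AR(1) beat-to-beat jitter added and the result clipped to the ceiling.
#' The first sample equals `initial_hr` exactly.
#'
#' @param sc A [scenario()].
#' @return Tibble with columns `t` (seconds from start, 1 Hz), `hr` (bpm)
#'   and `age` (years, constant).
#' @export
generate_hr_ramp <- function(sc) {
  ceil <- ramp_ceiling(sc$age)
  if (sc$initial_hr >= ceil) {
    abort(sprintf("initial_hr (%.1f) must be below the ramp ceiling of %.1f bpm (0.85 x (208 - 0.7 x age)).",
                  sc$initial_hr, ceil))
  }
  n <- sc$duration
  t <- seq_len(n) - 1
  t_sat <- max(1, 0.9 * (n - 1))
  trend <- pmin(sc$initial_hr + (ceil - sc$initial_hr) * t / t_sat, ceil)
  jitter <- withr::with_seed(sc$seed, {
    e <- numeric(n)
    innov <- rnorm(n, 0, sc$hr_jitter_sd)
    for (i in seq_len(n)[-1]) e[i] <- sc$hr_jitter_ar * e[i - 1] + innov[i]
    e
  })
  hr <- pmax(pmin(trend + jitter, ceil), 1)
  hr[1] <- sc$initial_hr
  tibble(t = t, hr = hr, age = sc$age)
}

#' Generate ground-truth per-second color signals
#'
#' Each raw channel follows
#' `baseline_c + coupling_c * maxHR%(t) + N(0, noise_sd)`, clipped to the
#' 8-bit range — the linear color-with-effort association the renderer
#' paints onto the forehead.
#'
#' @param hr Tibble from [generate_hr_ramp()] (columns `t`, `hr`, `age`).
#' @param sc The [scenario()].
#' @return Tibble with columns `t`, `maxhr_pct`, `R`, `G`, `B` (1 Hz).
#' @export
generate_channel_signals <- function(hr, sc) {
  if (length(sc$coupling) != 3L) abort("`coupling` must have 3 components.")
  pct <- max_hr_percent(hr$hr, hr$age)
  n <- nrow(hr)
  noise <- withr::with_seed(sc$seed + 1L, matrix(rnorm(3L * n, 0, sc$noise_sd), n, 3L))
  ch <- matrix(vapply(1:3, function(c) {
    pmin(pmax(sc$baseline_color[c] + sc$coupling[c] * pct + noise[, c], 0), 255)
  }, numeric(n)), nrow = n)
  tibble(t = hr$t, maxhr_pct = pct,
         R = ch[, 1], G = ch[, 2], B = ch[, 3])
}

# static geometry of the synthetic frontal face, all boxes 0-based half-open
face_geometry <- function(sc) {
  H <- sc$height; W <- sc$width
  face_h <- round(0.7 * H); face_w <- round(0.55 * face_h)
  if (face_h < 32 || face_w < 24 || face_w > W) {
    abort(sprintf("frame %dx%d too small to contain a usable face.", H, W))
  }
  fx <- round((W - face_w) / 2); fy <- round((H - face_h) / 2)
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  cx <- fx + face_w / 2 + 0.5; cy <- fy + face_h / 2 + 0.5
  ellipse <- ((col - cx) / (face_w / 2))^2 + ((row - cy) / (face_h / 2))^2 <= 1
  frac_box <- function(r0, r1, c0, c1) {
    row >= fy + r0 * face_h + 1 & row <= fy + r1 * face_h &
      col >= fx + c0 * face_w + 1 & col <= fx + c1 * face_w
  }
  band <- frac_box(0.08, 0.32, 0.25, 0.75) & ellipse
  features <- (frac_box(0.42, 0.52, 0.22, 0.40) | frac_box(0.42, 0.52, 0.60, 0.78) |
               frac_box(0.34, 0.38, 0.22, 0.40) | frac_box(0.34, 0.38, 0.60, 0.78)) & ellipse
  mouth <- frac_box(0.72, 0.78, 0.38, 0.62) & ellipse
  list(H = H, W = W, box = face_box(fx, fy, face_w, face_h, "ground_truth"),
       ellipse = ellipse, band = band, features = features, mouth = mouth,
       band_frac = c(r0 = 0.08, r1 = 0.32, c0 = 0.25, c1 = 0.75))
}

#' Render a synthetic session as a lazy frame stream
#'
#' Every frame holds an elliptical skin-tone face with dark eye/brow blobs
#' at a fixed, metadata-recorded location; the forehead band's color equals
#' the per-second ground-truth signal for that second (before flicker and
#' blur). A multiplicative sinusoidal brightness flicker of amplitude
#' `flicker_amplitude` is applied per frame, a seeded `blur_fraction` of
#' frames is convolved with the horizontal linear-motion kernel, optional
#' per-pixel sensor noise is added, and the frame is quantized to integers
#' (8-bit). Frame metadata records the ground-truth face box and the blur
#' flag.
#'
#' @param signals Tibble from [generate_channel_signals()], covering the
#'   full duration.
#' @param sc The [scenario()].
#' @return A [frame_source()].
#' @export
render_frames <- function(signals, sc) {
  if (nrow(signals) < sc$duration) {
    abort("`signals` must cover the full scenario duration.")
  }
  geo <- face_geometry(sc)
  fps <- as.integer(sc$frame_rate)
  n_frames <- sc$duration * fps
  skin0 <- as.numeric(signals[1, c("R", "G", "B")])
  base <- array(0, dim = c(geo$H, geo$W, 3))
  bg <- c(64, 64, 70); feat <- c(60, 45, 40); lips <- c(140, 85, 80)
  plane <- geo$H * geo$W
  e_idx <- which(geo$ellipse); f_idx <- which(geo$features)
  m_idx <- which(geo$mouth); b_idx <- which(geo$band)
  for (c in 1:3) {
    p <- base[, , c]
    p[] <- bg[c]
    p[e_idx] <- skin0[c]
    p[f_idx] <- feat[c]
    p[m_idx] <- lips[c]
    base[, , c] <- p
  }
  blurred <- withr::with_seed(sc$seed + 2L, runif(n_frames) < sc$blur_fraction)
  kblur <- motion_kernel(sc$blur_length, 0)
  sig <- as.matrix(signals[seq_len(sc$duration), c("R", "G", "B")])
  get_frame <- function(i) {
    if (i < 1L || i > n_frames) abort("frame index out of range.")
    s <- (i - 1L) %/% fps + 1L
    tt <- (i - 1L) / fps
    img <- base
    for (c in 1:3) img[b_idx + (c - 1L) * plane] <- sig[s, c]
    if (blurred[i]) {
      img <- .sep_conv2_3(img, geo$H, geo$W, kx = kblur[1, ], ky = 1)
    }
    factor <- 1 + sc$flicker_amplitude * sin(2 * pi * sc$flicker_freq * tt)
    if (sc$pixel_noise_sd > 0) {
      img <- img * factor +
        withr::with_seed((sc$seed + 100003 * as.numeric(i)) %% 2147483647,
                         array(rnorm(length(img), 0, sc$pixel_noise_sd), dim = dim(img)))
      factor <- 1
    }
    fr <- .mul_round_clip(img, factor)
    attr(fr, "t") <- tt
    attr(fr, "index") <- i
    fr
  }
  meta <- tibble(index = seq_len(n_frames), t = (seq_len(n_frames) - 1) / fps,
                 blurred = blurred,
                 box_x = geo$box$x, box_y = geo$box$y,
                 box_w = geo$box$w, box_h = geo$box$h)
  frame_source(n_frames, fps, geo$W, geo$H, get_frame, meta)
}
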