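# small-scale scenario for unit tests: same physics, cheaper frames
tiny_scenario <- function(duration = 10, seed = 42, width = 320, height = 180,
                          noise_sd = 0, flicker_amplitude = 0,
                          blur_fraction = 0, ...) {
  scenario(duration = duration, seed = seed, width = width, height = height,
           noise_sd = noise_sd, flicker_amplitude = flicker_amplitude,
           blur_fraction = blur_fraction, ...)
}

constant_frame <- function(color = c(120, 90, 60), h = 40, w = 50) {
  array(rep(color, each = h * w), dim = c(h, w, 3))
}

noise_frame <- function(h = 120, w = 160, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)))
}

# driven lag-1 recurrence with known coefficients, for identifiability checks
gen_recurrence <- function(n, a1 = 0.2, w1 = 0.9, wn = c(0.5, 0, 0),
                           noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    C <- matrix(runif(n * 3), n, 3)
    eps <- rnorm(n, 0, noise_sd)
    y <- numeric(n)
    y[1] <- 2
    for (t in 2:n) y[t] <- a1 + w1 * y[t - 1] + sum(wn * C[t - 1, ]) + eps[t]
    tibble::tibble(t = seq_len(n) - 1, y = y,
                   c1 = C[, 1], c2 = C[, 2], c3 = C[, 3])
  })
}

# ground-truth box of a frame source as a face_box
meta_box <- function(frames, i = 1) {
  m <- frames$meta[i, ]
  face_box(m$box_x, m$box_y, m$box_w, m$box_h, "ground_truth")
}
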