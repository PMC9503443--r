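test_that("ramp ceiling follows the 85% submaximal termination rule", {
  expect_equal(ramp_ceiling(20), 0.85 * 194)   # 208 - 0.7*20 = 194
  sc <- tiny_scenario(duration = 600, seed = 1, age = 20)
  hr <- generate_hr_ramp(sc)
  expect_length(hr$hr, 600)
  expect_true(all(hr$hr <= ramp_ceiling(20) + 1e-12))
  err <- expect_error(generate_hr_ramp(tiny_scenario(seed = 1, age = 20,
                                                     initial_hr = 170)),
                      "ceiling")
  expect_match(conditionMessage(err), "164.9")
})

test_that("the ramp starts at the recorded initial heart rate", {
  hr <- generate_hr_ramp(tiny_scenario(duration = 60, seed = 3, age = 22,
                                       initial_hr = 93))
  expect_equal(hr$hr[1], 93)
  expect_equal(hr$t, 0:59)
})

test_that("channel signals follow baseline + coupling * maxHR%", {
  sc0 <- tiny_scenario(duration = 120, seed = 4,
                       coupling = c(R = 0, G = 0, B = 0))
  hr <- generate_hr_ramp(sc0)
  sig <- generate_channel_signals(hr, sc0)
  expect_true(all(sig$R == sc0$baseline_color["R"]))
  expect_true(all(sig$G == sc0$baseline_color["G"]))

  scn <- tiny_scenario(duration = 120, seed = 4,
                       coupling = c(R = -0.5, G = 0, B = 0))
  sign <- generate_channel_signals(generate_hr_ramp(scn), scn)
  up <- diff(sign$maxhr_pct) > 0
  expect_true(all(diff(sign$R)[up] < 0))
})

test_that("least squares on generated pairs recovers the coupling slope", {
  sc <- tiny_scenario(duration = 600, seed = 5, noise_sd = 2,
                      coupling = c(R = 0.25, G = -0.05, B = -0.05))
  sig <- generate_channel_signals(generate_hr_ramp(sc), sc)
  for (ch in c("R", "G", "B")) {
    fit <- summary(lm(sig[[ch]] ~ sig$maxhr_pct))$coefficients
    expect_lt(abs(fit[2, 1] - sc$coupling[ch]), 3 * fit[2, 2])
  }
})

test_that("rendering is exact when all corruptions are off", {
  sim <- simulate_session(tiny_scenario(duration = 2, seed = 6))
  fr <- sim$frames$get_frame(1)
  expect_equal(dim(fr), c(180, 320, 3))
  expect_true(all(fr == round(fr)))          # 8-bit quantized
  crop <- crop_resize_face(fr, meta_box(sim$frames))
  patch <- extract_forehead_patch(crop)
  got <- vapply(1:3, function(c) patch_average(patch[, , c]), numeric(1))
  expect_true(all(abs(got - as.numeric(sim$signals[1, c("R", "G", "B")])) <= 0.5))
})

test_that("blur flags and frame metadata are faithful", {
  sim <- simulate_session(tiny_scenario(duration = 2, seed = 8, blur_fraction = 1))
  expect_true(all(sim$frames$meta$blurred))
  sim0 <- simulate_session(tiny_scenario(duration = 2, seed = 8))
  expect_false(any(sim0$frames$meta$blurred))
  expect_error(render_frames(sim0$signals,
                             tiny_scenario(duration = 2, seed = 8, width = 20,
                                           height = 12)),
               "too small")
})

test_that("flicker modulates per-frame forehead brightness with CV ~ A/sqrt(2)", {
  A <- 0.05
  sc <- tiny_scenario(duration = 1, seed = 9, flicker_amplitude = A)
  frames <- simulate_session(sc)$frames
  box <- meta_box(frames)
  bright <- vapply(1:25, function(i) {
    crop <- crop_resize_face(frames$get_frame(i), box)
    patch <- extract_forehead_patch(crop)
    mean(patch)
  }, numeric(1))
  cv <- sd(bright) / mean(bright)
  expect_equal(cv, A / sqrt(2), tolerance = 0.1)
})

test_that("identical scenarios produce identical sessions", {
  a <- simulate_session(tiny_scenario(duration = 3, seed = 10, noise_sd = 1,
                                      blur_fraction = 0.3, flicker_amplitude = 0.02))
  b <- simulate_session(tiny_scenario(duration = 3, seed = 10, noise_sd = 1,
                                      blur_fraction = 0.3, flicker_amplitude = 0.02))
  expect_identical(a$hr, b$hr)
  expect_identical(a$signals, b$signals)
  expect_identical(a$frames$get_frame(17), b$frames$get_frame(17))
})

test_that("the corruption-free pipeline returns ground truth within quantization", {
  sim <- simulate_session(tiny_scenario(duration = 6, seed = 11))
  sig <- extract_signals(sim$frames, box = "ground_truth")
  got <- sig |>
    dplyr::filter(model == "RGB") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  want <- signals_from_ground_truth(sim$signals) |>
    dplyr::filter(model == "RGB") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  for (ch in c("R", "G", "B")) {
    expect_true(all(abs(got[[ch]] - want[[ch]]) < 0.6))
  }
})
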