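test_that("ground-truth boxes bypass detection verbatim", {
  fr <- noise_frame(seed = 31)
  gb <- face_box(10, 12, 50, 60, "ground_truth")
  b <- detect_face(fr, ground_truth = gb)
  expect_equal(b[c("x", "y", "w", "h")], gb[c("x", "y", "w", "h")])
  expect_equal(b$source, "ground_truth")
})

test_that("pure-noise frames raise a no-face error carrying the frame index", {
  fr <- new_frame(noise_frame(seed = 32), t = 1.2, index = 31L)
  err <- expect_error(detect_face(fr), class = "facehr_no_face")
  expect_equal(err$frame_index, 31L)
})

test_that("the detector overlaps the rendered ground-truth face (IoU > 0.3)", {
  for (s in c(1, 2, 3)) {
    frames <- simulate_session(tiny_scenario(duration = 1, seed = s))$frames
    det <- detect_face(frames$get_frame(1))
    expect_equal(det$source, "detected")
    expect_gt(box_iou(det, meta_box(frames)), 0.3)
  }
})

test_that("crop-and-resize honors the fixed output size and identity case", {
  fr <- noise_frame(h = 500, w = 500, seed = 33)
  # identity: a 400x400 box comes back exactly
  b400 <- face_box(30, 40, 400, 400)
  expect_equal(crop_resize_face(fr, b400),
               fr[41:440, 31:430, , drop = FALSE], ignore_attr = TRUE)
  # constant box upsamples to the same constant
  cfr <- constant_frame(c(10, 200, 30), h = 300, w = 300)
  out <- crop_resize_face(cfr, face_box(50, 50, 200, 200))
  expect_equal(dim(out), c(400, 400, 3))
  expect_true(all(out[, , 1] == 10 & out[, , 2] == 200 & out[, , 3] == 30))
  # aspect ratio is not preserved: any box lands on 400x400
  out2 <- crop_resize_face(fr, face_box(0, 0, 100, 200))
  expect_equal(dim(out2), c(400, 400, 3))
  expect_error(crop_resize_face(fr, face_box(450, 450, 100, 100)),
               "outside the frame")
})

test_that("forehead patch extraction is an exact axis-aligned crop", {
  fr <- noise_frame(h = 400, w = 400, seed = 34)
  expect_equal(extract_forehead_patch(fr, patch_spec(0.5, 0.5, 400)), fr,
               ignore_attr = TRUE)
  px <- extract_forehead_patch(fr, patch_spec(0.3, 0.7, 1))
  expect_equal(as.numeric(px), as.numeric(fr[281, 121, ]))
  p16 <- extract_forehead_patch(fr)
  expect_equal(dim(p16), c(16, 16, 3))
  expect_error(extract_forehead_patch(fr, patch_spec(0.99, 0.5, 32)),
               "exceeds the crop")
  expect_error(patch_spec(size = 0), ">= 1")
})

test_that("the default patch lies inside the rendered forehead band", {
  frames <- simulate_session(tiny_scenario(duration = 1, seed = 7))$frames
  box <- meta_box(frames)
  # band rows 8%-32%, cols 25%-75% of the face box (renderer geometry)
  spec <- patch_spec()
  cy <- floor(spec$cy_frac * 400); cx <- floor(spec$cx_frac * 400)
  rows <- (cy - 8 + seq_len(16)) / 400
  cols <- (cx - 8 + seq_len(16)) / 400
  expect_true(all(rows > 0.08 & rows < 0.32))
  expect_true(all(cols > 0.25 & cols < 0.75))
  # and its mean equals the painted ground-truth color after quantization
  crop <- crop_resize_face(frames$get_frame(1), box)
  patch <- extract_forehead_patch(crop, spec)
  truth <- as.numeric(simulate_session(tiny_scenario(duration = 1, seed = 7))$signals[1, c("R", "G", "B")])
  got <- vapply(1:3, function(c) patch_average(patch[, , c]), numeric(1))
  expect_true(all(abs(got - truth) <= 0.5))
})

test_that("patch mean of a constant-color face is exact", {
  cfr <- constant_frame(c(123, 45, 67), h = 400, w = 400)
  patch <- extract_forehead_patch(cfr)
  expect_equal(vapply(1:3, function(c) patch_average(patch[, , c]), numeric(1)),
               c(123, 45, 67))
})
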