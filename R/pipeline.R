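#' Pipeline configuration
#'
#' One validated bag of stage parameters: preprocessing (blur statistic and
#' threshold, deconvolution PSF, denoising), face/patch localisation,
#' smoothing windows, and regression options.
#'
#' @param blur_threshold Sharpness threshold below which a frame counts as
#'   blurred (variance units; default 100).
#' @param blur_stat `"laplacian"` (variance of the Laplacian) or
#'   `"pixel_variance"`.
#' @param deblur Apply Wiener deconvolution to frames flagged as blurred
#'   (`"flagged"`, default), to `"all"` frames, or `"never"`.
#' @param psf_length,psf_angle Linear-motion PSF parameters for
#'   deconvolution.
#' @param nsr Wiener noise-to-signal ratio.
#' @param gaussian_sigma Denoising Gaussian SD in pixels (0 disables).
#' @param face_min_size Minimum face box side accepted by detection.
#' @param patch_cx_frac,patch_cy_frac,patch_size Forehead patch placement,
#'   see [patch_spec()].
#' @param crop_size Face crop side length (default 400).
#' @param median_window,median_pad Median smoothing window and reflection
#'   pad (samples at 1 Hz).
#' @param ma_window Moving-average window (samples at 1 Hz).
#' @param normalize_y Min-max normalize the dependent maxHR% as well
#'   (default FALSE: maxHR% is modelled on its natural percent scale).
#' @return A `facehr_config` list.
#' @export
pipeline_config <- function(blur_threshold = 100,
                            blur_stat = c("laplacian", "pixel_variance"),
                            deblur = c("flagged", "all", "never"),
                            psf_length = 9, psf_angle = 0, nsr = 0.01,
                            gaussian_sigma = 1,
                            face_min_size = 40,
                            patch_cx_frac = 0.5, patch_cy_frac = 0.18,
                            patch_size = 16, crop_size = 400,
                            median_window = 201, median_pad = 40,
                            ma_window = 21, normalize_y = FALSE) {
  blur_stat <- match.arg(blur_stat)
  deblur <- match.arg(deblur)
  if (blur_threshold <= 0) abort("`blur_threshold` must be > 0.")
  if (median_window %% 2 == 0) abort("`median_window` must be odd.")
  if (ma_window < 1) abort("`ma_window` must be >= 1.")
  structure(as.list(environment()), class = "facehr_config")
}

#' Simulate a full synthetic session
#'
#' Generates the heart-rate ramp, the coupled ground-truth color signals,
#' and the lazy rendered frame stream for a scenario. Optionally writes the
#' artifacts to `dir`: `ground_truth.csv` (t, hr, maxHR%, R, G, B),
#' `scenario.yaml`, and (if `write_frames`) numbered PNG frames plus a
#' `frames.csv` metadata table. Identical scenarios produce byte-identical
#' artifacts.
#'
#' @param sc A [scenario()] (its seed drives all randomness).
#' @param dir Optional output directory (created if needed).
#' @param write_frames Also write each rendered frame as PNG (large; only
#'   sensible for short scenarios).
#' @return List with `hr` (tibble), `signals` (tibble), `frames`
#'   ([frame_source()]) and `paths` (written files, if any).
#' @export
simulate_session <- function(sc, dir = NULL, write_frames = FALSE) {
  hr <- generate_hr_ramp(sc)
  signals <- generate_channel_signals(hr, sc)
  frames <- render_frames(signals, sc)
  paths <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gt <- dplyr::inner_join(hr, signals, by = "t")
    gt_path <- file.path(dir, "ground_truth.csv")
    write.csv(gt[, c("t", "hr", "maxhr_pct", "R", "G", "B")], gt_path,
              row.names = FALSE)
    sc_path <- file.path(dir, "scenario.yaml")
    yaml::write_yaml(unclass(sc), sc_path)
    paths <- c(ground_truth = gt_path, scenario = sc_path)
    if (write_frames) {
      write.csv(frames$meta, file.path(dir, "frames.csv"), row.names = FALSE)
      for (i in seq_len(frames$n_frames)) {
        frame_to_png(frames$get_frame(i),
                     file.path(dir, sprintf("frame_%06d.png", i)))
      }
      paths <- c(paths, frames_dir = dir)
    }
  }
  list(hr = hr, signals = signals, frames = frames, paths = paths)
}

#' Read a scenario back from YAML
#'
#' @param path Path to a `scenario.yaml` written by [simulate_session()].
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(scenario, v[setdiff(names(v), character(0))])
}

# per-frame processing: preprocess, localise, normalize, convert, average.
# Returns the 15 channel values for one frame plus the box/blur log entry.
process_frame <- function(frame, cfg, box) {
  blurred <- is_blurred(frame, cfg$blur_threshold, cfg$blur_stat)
  if ((cfg$deblur == "flagged" && blurred) || cfg$deblur == "all") {
    frame <- wiener_deblur(frame, motion_kernel(cfg$psf_length, cfg$psf_angle),
                           cfg$nsr)
  }
  if (cfg$gaussian_sigma > 0) frame <- gaussian_denoise(frame, cfg$gaussian_sigma)
  crop <- crop_resize_face(frame, box, cfg$crop_size)
  patch <- extract_forehead_patch(
    crop, patch_spec(cfg$patch_cx_frac, cfg$patch_cy_frac, cfg$patch_size))
  norm <- normalize_rgb(patch)
  vals <- unlist(lapply(COLOR_MODELS, function(m) {
    conv <- convert_color(norm, m)
    vapply(1:3, function(c) patch_average(conv[, , c]), numeric(1))
  }))
  list(values = vals, blurred = blurred)
}

#' Extract per-second color signals from a frame stream
#'
#' Runs the full extraction chain on every frame — blur detection,
#' conditional Wiener deconvolution, Gaussian denoising, face localisation,
#' 400 x 400 crop, forehead patch, chromaticity normalization, conversion to
#' all five color models, patch averaging — then block-averages the
#' per-frame samples to 1 Hz. When detection fails in a frame the most
#' recent successful box is reused (temporal hold, logged); if no frame ever
#' yields a face and no `manual_box` is given, extraction fails.
#'
#' @param frames A [frame_source()].
#' @param cfg A [pipeline_config()].
#' @param box `"detect"` to run face detection, `"ground_truth"` to use the
#'   source's metadata boxes (synthetic streams).
#' @param manual_box Optional fixed [face_box()] used for every frame.
#' @return Tidy tibble with columns `t`, `model`, `channel`, `value`
#'   (15 series at 1 Hz). The per-frame log (blur flags, boxes, detection
#'   fallbacks) is attached as attribute `"log"`.
#' @export
extract_signals <- function(frames, cfg = pipeline_config(),
                            box = c("detect", "ground_truth"),
                            manual_box = NULL) {
  box <- match.arg(box)
  n <- frames$n_frames
  if (n < frames$fps) abort("frame stream shorter than one second.")
  chan_names <- unlist(lapply(COLOR_MODELS, model_channels))
  model_names <- rep(COLOR_MODELS, each = 3)
  vals <- matrix(NA_real_, n, 15L)
  log <- tibble(index = seq_len(n), blurred = NA, held = FALSE,
                box_x = NA_integer_, box_y = NA_integer_,
                box_w = NA_integer_, box_h = NA_integer_)
  last_box <- manual_box
  for (i in seq_len(n)) {
    fr <- frames$get_frame(i)
    b <- if (!is.null(manual_box)) {
      manual_box
    } else if (box == "ground_truth") {
      m <- frames$meta[i, ]
      if (is.na(m$box_x)) abort("frame source carries no ground-truth boxes.")
      face_box(m$box_x, m$box_y, m$box_w, m$box_h, "ground_truth")
    } else {
      tryCatch(detect_face(fr, min_size = cfg$face_min_size),
               facehr_no_face = function(e) NULL)
    }
    if (is.null(b)) {
      if (is.null(last_box)) {
        abort(sprintf("no face detected up to frame %d and no manual box given.", i),
              class = "facehr_no_face")
      }
      b <- last_box
      log$held[i] <- TRUE
    }
    last_box <- b
    res <- process_frame(fr, cfg, b)
    vals[i, ] <- res$values
    log$blurred[i] <- res$blurred
    log[i, c("box_x", "box_y", "box_w", "box_h")] <-
      as.list(c(b$x, b$y, b$w, b$h))
  }
  out <- purrr::map_dfr(seq_len(15L), function(k) {
    v <- resample_to_1hz(vals[, k], frames$fps)
    tibble(t = seq_along(v) - 1, model = model_names[k],
           channel = chan_names[k], value = v)
  })
  attr(out, "log") <- log
  out
}

#' Ground-truth signals pushed through the signal-domain pipeline
#'
#' The oracle route for end-to-end checks: applies the same chromaticity
#' normalization the image pipeline performs to the generator's raw
#' per-second channel signals (no rendering, no optics), then converts to
#' all five models. One "pixel" per second.
#'
#' @param signals Tibble from [generate_channel_signals()].
#' @return Tidy tibble like [extract_signals()] output.
#' @export
signals_from_ground_truth <- function(signals) {
  n <- nrow(signals)
  arr <- array(c(signals$R, signals$G, signals$B), dim = c(n, 1, 3))
  norm <- normalize_rgb(arr)
  purrr::map_dfr(COLOR_MODELS, function(m) {
    conv <- convert_color(norm, m)
    purrr::map_dfr(1:3, function(c) {
      tibble(t = signals$t, model = m, channel = model_channels(m)[c],
             value = conv[, 1, c])
    })
  })
}

#' Smooth extracted signals
#'
#' Applies the two-stage chain to each model/channel series: sliding median
#' (reflection-padded) then causal moving average.
#'
#' @param signals Tidy signals tibble (`t`, `model`, `channel`, `value`).
#' @param cfg A [pipeline_config()] supplying the windows.
#' @return Tibble of the same shape with smoothed `value`.
#' @export
smooth_signals <- function(signals, cfg = pipeline_config()) {
  signals |>
    group_by(.data$model, .data$channel) |>
    arrange(.data$t, .by_group = TRUE) |>
    mutate(value = moving_average(
      median_smooth(.data$value, cfg$median_window, cfg$median_pad),
      min(cfg$ma_window, dplyr::n()))) |>
    ungroup()
}

#' Build per-model design tables
#'
#' Inner-joins the smoothed signals with the heart-rate series on integer
#' seconds, converts heart rate to maxHR%, min-max normalizes each channel
#' to `[0, 1]`, and returns one design tibble per color model (columns `t`,
#' `y`, three channels, `participant`, `age`).
#'
#' @param signals Tidy (smoothed) signals tibble.
#' @param hr Tibble with columns `t`, `hr`, `age` (1 Hz).
#' @param participant Participant label.
#' @param cfg A [pipeline_config()]; with `normalize_y = TRUE` the dependent
#'   variable is min-max normalized too.
#' @return Named list of design tibbles, one per color model.
#' @export
design_tables <- function(signals, hr, participant = "P1",
                          cfg = pipeline_config()) {
  joined <- inner_join(signals, hr, by = "t")
  if (nrow(joined) == 0L) {
    abort(sprintf("empty join: signals cover t in [%s, %s], hr covers [%s, %s].",
                  min(signals$t), max(signals$t), min(hr$t), max(hr$t)))
  }
  age <- hr$age[1]
  out <- lapply(COLOR_MODELS, function(m) {
    sub <- joined |> filter(.data$model == m)
    wide <- sub |>
      select("t", "hr", "channel", "value") |>
      tidyr::pivot_wider(names_from = "channel", values_from = "value") |>
      arrange(.data$t)
    chans <- model_channels(m)
    y <- max_hr_percent(wide$hr, age)
    if (cfg$normalize_y) y <- minmax_normalize(y)
    tibble(t = wide$t, y = y,
           !!!setNames(lapply(chans, function(ch) minmax_normalize(wide[[ch]])),
                       chans),
           participant = participant, age = age)
  })
  setNames(out, COLOR_MODELS)
}

#' Fit the personalized and universal models for a cohort of sessions
#'
#' For every participant and color model, fits the lag-1 multivariate
#' autoregression (personalized model) and collects its RMSE into a
#' participant-by-model matrix with a closing `AVG` row (true column
#' means). Across participants it fits the pooled degree-3 polynomial model
#' per color model and computes the VIF report of each model's pooled
#' channels. With a single participant the universal model is skipped with
#' a warning.
#'
#' @param designs Named list: one element per participant, each a named
#'   list of per-model design tibbles (from [design_tables()]).
#' @param degree Polynomial degree of the universal model.
#' @param method Universal-model estimator, see [fit_poly_global()].
#' @return List with `rmse_matrix` (tibble), `ar_fits` (nested list),
#'   `universal` (per-model `poly_fit` or NULL), `vif` (per-model tibble).
#' @export
fit_models <- function(designs, degree = 3, method = "ridge") {
  stopifnot(length(designs) >= 1L)
  ids <- names(designs) %||% paste0("P", seq_along(designs))
  ar_fits <- lapply(designs, function(d) lapply(d, fit_ar1))
  rmse_rows <- purrr::map_dfr(seq_along(designs), function(i) {
    tibble(participant = ids[i],
           !!!lapply(ar_fits[[i]], function(f) f$rmse))
  })
  avg <- tibble(participant = "AVG",
                !!!lapply(rmse_rows[COLOR_MODELS], mean))
  rmse_matrix <- bind_rows(rmse_rows, avg)
  universal <- NULL
  vif <- NULL
  if (length(designs) >= 2L) {
    universal <- lapply(COLOR_MODELS, function(m) {
      fit_poly_global(lapply(designs, `[[`, m), degree = degree, method = method)
    })
    names(universal) <- COLOR_MODELS
  } else {
    warn("single participant: universal (pooled) model skipped.")
  }
  vif <- lapply(COLOR_MODELS, function(m) {
    pooled <- bind_rows(lapply(designs, `[[`, m))
    vif_report(pooled[, model_channels(m)], pooled$y)
  })
  names(vif) <- COLOR_MODELS
  list(rmse_matrix = rmse_matrix, ar_fits = ar_fits,
       universal = universal, vif = vif)
}

#' Write a model report as JSON
#'
#' Serializes the universal-model metrics, AR RMSE matrix and VIF tables of
#' a [fit_models()] result.
#'
#' @param report A [fit_models()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  out <- list(
    rmse_matrix = report$rmse_matrix,
    universal = if (!is.null(report$universal)) {
      lapply(report$universal, function(f) {
        list(rmse = f$rmse, r_squared = f$r_squared, f_stat = f$f_stat,
             df = f$df, p_value = f$p_value,
             coefficients = as.list(f$coefficients))
      })
    },
    vif = report$vif
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Nine-participant example cohort
#'
#' The cycling-cohort descriptors used throughout the package's examples
#' and checks: age, weight (kg), height (cm), initial and final heart rate
#' (bpm) and ramp duration (s) for nine participants.
#'
#' @return Tibble with one row per participant.
#' @export
example_cohort <- function() {
  path <- system.file("extdata", "cohort.csv", package = "facehr", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
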