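#' Plot extracted color signals
#'
#' One panel per color model, per-second channel traces over exercise time.
#'
#' @param signals Tidy signals tibble (`t`, `model`, `channel`, `value`).
#' @return A ggplot object.
#' @export
plot_signals <- function(signals) {
  ggplot2::ggplot(signals,
                  ggplot2::aes(x = .data$t, y = .data$value,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$model), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "channel value",
                  title = "Forehead-patch color signals") +
    ggplot2::theme_minimal()
}

#' Plot combined color intensity against heart rate
#'
#' The luminance-weighted combined intensity of the (already extracted)
#' RGB-model signals against min-max normalized heart rate, both at 1 Hz.
#'
#' @param signals Tidy signals tibble containing the RGB model.
#' @param hr Tibble with columns `t`, `hr`.
#' @return A ggplot object.
#' @export
plot_intensity_vs_hr <- function(signals, hr) {
  rgbw <- signals |>
    filter(.data$model == "RGB") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value") |>
    inner_join(hr, by = "t") |>
    mutate(intensity = combined_intensity(.data$R, .data$G, .data$B),
           hr_norm = minmax_normalize(.data$hr))
  ggplot2::ggplot(rgbw, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = minmax_normalize(.data$intensity),
                                    colour = "combined intensity")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hr_norm, colour = "normalized HR")) +
    ggplot2::labs(x = "time (s)", y = "normalized value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_ar1 Observed vs fitted maxHR% over time.
#' @param object An `ar1_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ar1_fit <- function(object, ...) {
  d <- tibble(t = seq_len(object$n - 1L),
              observed = object$lm$model$.y,
              fitted = stats::fitted(object$lm))
  d <- tidyr::pivot_longer(d, c("observed", "fitted"),
                           names_to = "series", values_to = "y")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$y,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "maxHR%",
                  title = "Lag-1 autoregression: observed vs fitted") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_poly_global Predicted vs observed maxHR% for the pooled
#'   polynomial model.
#' @param object A `poly_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.poly_fit <- function(object, ...) {
  d <- tibble(observed = object$y, predicted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed maxHR%", y = "predicted maxHR%",
                  title = sprintf("Pooled degree-%d model (RMSE %.2f, R2 %.2f)",
                                  object$degree, object$rmse, object$r_squared)) +
    ggplot2::theme_minimal()
}
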