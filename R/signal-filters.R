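#' Resample a uniformly sampled signal to 1 Hz by block averaging
#'
#' Each output sample is the mean of one whole second of input samples; a
#' trailing partial second is dropped.
#'
#' @param x Numeric vector sampled at `rate` Hz.
#' @param rate Input sampling rate in Hz (samples per second, integer).
#' @return Numeric vector at 1 Hz, length `floor(length(x) / rate)`.
#' @export
resample_to_1hz <- function(x, rate = 25) {
  if (length(x) == 0L) abort("cannot resample an empty signal.")
  rate <- as.integer(rate)
  if (rate < 1L) abort("`rate` must be a positive integer.")
  n_sec <- length(x) %/% rate
  if (n_sec == 0L) abort("signal shorter than one second at this rate.")
  blocks <- matrix(x[seq_len(n_sec * rate)], nrow = rate)
  colMeans(blocks)
}

#' Sliding-window median smoothing with reflection padding
#'
#' Running median with an odd window. The endpoint problem is handled by
#' reflecting the first/last `pad` samples about each end (mirror, without
#' duplicating the edge sample) and edge-replicating any remaining shortfall
#' when the half-window exceeds `pad`. If the window exceeds the signal
#' length it shrinks to the largest odd number not exceeding the length
#' (with a message), so short recordings remain processable.
#'
#' @param x Numeric vector.
#' @param window Odd window length in samples (default 201).
#' @param pad Number of samples reflected at each end (default 40).
#' @return Smoothed vector, same length as `x`.
#' @export
median_smooth <- function(x, window = 201, pad = 40) {
  n <- length(x)
  if (n == 0L) abort("empty signal.")
  window <- as.integer(window)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  if (window < 1L) abort("`window` must be >= 1.")
  if (window > n) {
    window <- if (n %% 2L == 1L) n else n - 1L
    if (window < 1L) window <- 1L
    inform(sprintf("median window shrunk to %d for a length-%d signal.", window, n))
  }
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  padded <- pad_reflect(x, half, pad)
  sm <- stats::runmed(padded, k = window, endrule = "keep")
  sm[(half + 1L):(half + n)]
}

# reflect `pad` samples (mirror about the end sample, excluding it), then
# edge-replicate out to `half` samples each side
pad_reflect <- function(x, half, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L, half)
  left <- if (pad > 0L) x[(pad + 1L):2L] else numeric(0)
  right <- if (pad > 0L) x[(n - 1L):(n - pad)] else numeric(0)
  extra <- half - pad
  if (extra > 0L) {
    left <- c(rep(x[1L], extra), left)
    right <- c(right, rep(x[n], extra))
  }
  c(left, x, right)
}

#' Causal moving-average smoothing
#'
#' The output at position `n` is the mean of the current sample and the
#' previous `ws - 1` samples. The first `ws - 1` outputs are computed on a
#' reflected prefix so the output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param ws Window size in samples (default 21).
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, ws = 21) {
  n <- length(x)
  ws <- as.integer(ws)
  if (ws < 1L) abort("`ws` must be >= 1.")
  if (ws > n) abort(sprintf("`ws` (%d) exceeds the signal length (%d).", ws, n))
  if (ws == 1L) return(x)
  prefix <- x[ws:2L]                       # mirror, edge sample not repeated
  padded <- c(prefix, x)
  cs <- cumsum(padded)
  idx <- ws:(ws + n - 1L)
  (cs[idx] - c(0, cs[seq_len(n - 1L)])) / ws
}

#' Min-max normalization to the unit interval
#'
#' `(v - min) / (max - min)`; a constant vector maps to all 0.5 (the
#' documented degenerate-case sentinel, keeping downstream regressions
#' finite).
#'
#' @param v Numeric vector.
#' @return Vector in `[0, 1]`.
#' @export
minmax_normalize <- function(v) {
  if (length(v) == 0L) abort("empty vector.")
  r <- range(v)
  if (r[1] == r[2]) return(rep(0.5, length(v)))
  (v - r[1]) / (r[2] - r[1])
}
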