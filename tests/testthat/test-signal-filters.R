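test_that("1 Hz resampling averages whole-second blocks and drops the tail", {
  expect_equal(resample_to_1hz(rep(7.5, 25), 25), 7.5)
  expect_equal(resample_to_1hz(c(rep(1, 25), rep(3, 25)), 25), c(1, 3))
  expect_length(resample_to_1hz(seq_len(30), 25), 1)   # trailing 5 dropped
  expect_equal(resample_to_1hz(seq_len(30), 25), mean(1:25))
  expect_error(resample_to_1hz(numeric(0), 25), "empty")
})

test_that("median smoothing matches a brute-force oracle with the documented padding", {
  # independent oracle: build the padded vector by the documented rule, then
  # take plain medians of every window
  oracle <- function(x, window, pad) {
    n <- length(x); half <- (window - 1) / 2
    pad <- min(pad, n - 1, half)
    left <- if (pad > 0) x[(pad + 1):2] else numeric(0)
    right <- if (pad > 0) x[(n - 1):(n - pad)] else numeric(0)
    extra <- half - pad
    if (extra > 0) {
      left <- c(rep(x[1], extra), left)
      right <- c(right, rep(x[n], extra))
    }
    p <- c(left, x, right)
    vapply(seq_len(n), function(i) median(p[i:(i + window - 1)]), numeric(1))
  }
  expect_equal(median_smooth(c(1, 9, 2, 8, 3), window = 3, pad = 1)[2:4],
               c(2, 8, 3))                       # interior brute-force medians
  expect_equal(median_smooth(c(4, 1, 7), window = 1), c(4, 1, 7))
  expect_equal(median_smooth(rep(2, 30), window = 7), rep(2, 30))
  expect_error(median_smooth(1:10, window = 4), "odd")
  for (s in 1:20) {
    x <- withr::with_seed(s, rnorm(60))
    expect_equal(median_smooth(x, window = 9, pad = 3), oracle(x, 9, 3))
    expect_equal(median_smooth(x, window = 15, pad = 4), oracle(x, 15, 4))
  }
})

test_that("median window shrinks for short signals, with a message", {
  x <- withr::with_seed(1, rnorm(20))
  expect_message(y <- median_smooth(x, window = 201, pad = 40), "shrunk")
  expect_length(y, 20)
  expect_true(all(y >= min(x) & y <= max(x)))
})

test_that("causal moving average matches the brute-force reflected-prefix oracle", {
  oracle <- function(x, ws) {
    p <- c(x[ws:2], x)
    vapply(seq_along(x), function(i) mean(p[i:(i + ws - 1)]), numeric(1))
  }
  expect_equal(moving_average(c(1, 2, 3, 4), ws = 2)[2:4], c(1.5, 2.5, 3.5))
  expect_equal(moving_average(c(5, 1), ws = 1), c(5, 1))
  expect_equal(moving_average(rep(3, 25), ws = 7), rep(3, 25))
  expect_error(moving_average(1:5, ws = 6), "exceeds")
  for (s in 1:20) {
    x <- withr::with_seed(100 + s, rnorm(40))
    ws <- withr::with_seed(200 + s, sample(2:10, 1))
    expect_equal(moving_average(x, ws), oracle(x, ws))
  }
})

test_that("smoothing filters preserve length and stay within the input range", {
  for (s in 1:10) {
    x <- withr::with_seed(300 + s, rnorm(80))
    for (y in list(median_smooth(x, 11, 4), moving_average(x, 5))) {
      expect_length(y, 80)
      expect_true(all(is.finite(y)))
      expect_true(all(y >= min(x) - 1e-12 & y <= max(x) + 1e-12))
    }
  }
})

test_that("min-max normalization maps to [0,1] with the constant-vector sentinel", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5)), c(0.5, 0.5))
  x <- withr::with_seed(4, rnorm(50))
  y <- minmax_normalize(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
})
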