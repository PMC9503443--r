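test_that("maxHR% follows HR * 100 / (220 - age)", {
  expect_equal(max_hr_percent(110, 20), 55)
  expect_equal(max_hr_percent(191, 22), 191 * 100 / 198)
  expect_equal(max_hr_percent(220 - 35, 35), 100)
  expect_error(max_hr_percent(100, 220), "< 220")
  expect_error(max_hr_percent(0, 30), "> 0")
})

test_that("ADF statistic and p-value match the frozen reference values", {
  # reference: Dickey-Fuller regression with constant on these exact seeded
  # series, statistic and MacKinnon p computed with an independent
  # implementation during development and frozen here
  wn <- withr::with_seed(101, rnorm(300))
  rw <- withr::with_seed(202, cumsum(rnorm(300)))
  ar <- withr::with_seed(303, {
    e <- rnorm(300); x <- numeric(300)
    for (i in 2:300) x[i] <- 0.5 * x[i - 1] + e[i]
    x
  })
  r_wn <- adf_test(wn, max_lag = 6)
  expect_equal(r_wn$statistic, -17.4212281271, tolerance = 1e-8)
  expect_true(r_wn$stationary)
  r_rw <- adf_test(rw, max_lag = 6)
  expect_equal(r_rw$statistic, -1.7335025169, tolerance = 1e-8)
  expect_equal(r_rw$p_value, 0.4139388489, tolerance = 1e-7)
  expect_false(r_rw$stationary)
  r_ar <- adf_test(ar, max_lag = 6)
  expect_equal(r_ar$statistic, -10.0797497127, tolerance = 1e-8)
  expect_true(r_ar$stationary)
})

test_that("constant series is reported degenerate and stationary", {
  r <- adf_test(rep(4, 50))
  expect_true(r$stationary)
  expect_match(r$note, "degenerate")
})

test_that("lag-1 autoregression equals the normal-equations oracle", {
  for (s in 1:10) {
    tb <- gen_recurrence(40, noise_sd = 0.3, seed = 400 + s)
    fit <- fit_ar1(tb)
    n <- nrow(tb)
    M <- cbind(1, tb$y[-n], tb$c1[-n], tb$c2[-n], tb$c3[-n])
    beta <- solve(t(M) %*% M, t(M) %*% tb$y[-1])
    expect_equal(unname(c(fit$a1, fit$w1, fit$wn)), as.numeric(beta),
                 tolerance = 1e-8)
  }
})

test_that("a noiseless recurrence is identified exactly", {
  tb <- gen_recurrence(200, a1 = 0.2, w1 = 0.9, wn = c(0.5, 0, 0), seed = 77)
  fit <- fit_ar1(tb)
  expect_equal(c(fit$a1, fit$w1, unname(fit$wn)),
               c(0.2, 0.9, 0.5, 0, 0), tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  expect_length(fit$residuals, 199)
})

test_that("noisy recovery lands within 3 standard errors", {
  tb <- gen_recurrence(600, noise_sd = 0.05, seed = 88)
  est <- tidy(fit_ar1(tb))
  truth <- c(0.2, 0.9, 0.5, 0, 0)
  expect_true(all(abs(est$estimate - truth) < 3 * est$std.error))
})

test_that("constant predictors are rejected with the offending column named", {
  tb <- gen_recurrence(50, seed = 9)
  tb$c2 <- 0.4
  err <- expect_error(fit_ar1(tb), class = "facehr_rank_deficient")
  expect_match(conditionMessage(err), "c2")
})

test_that("one-step predictions are consistent with the training fit", {
  tb <- gen_recurrence(120, noise_sd = 0.1, seed = 10)
  fit <- fit_ar1(tb)
  pred <- predict(fit, tb)
  expect_equal(attr(pred, "rmse"), fit$rmse, tolerance = 1e-12)
  expect_equal(pred$.fitted + fit$residuals, pred$y, tolerance = 1e-10)
  tb2 <- tb
  names(tb2)[names(tb2) == "c3"] <- "c9"
  expect_error(predict(fit, tb2), "channel mismatch")
})

test_that("breaking temporal alignment does not improve noiseless predictions", {
  tb <- gen_recurrence(150, a1 = 0.1, w1 = 0.5, wn = c(0.8, -0.4, 0.3), seed = 11)
  fit <- fit_ar1(tb)
  base_rmse <- attr(predict(fit, tb), "rmse")
  for (s in 1:20) {
    shuf <- tb
    idx <- withr::with_seed(500 + s, sample(nrow(tb)))
    shuf[, c("c1", "c2", "c3")] <- shuf[idx, c("c1", "c2", "c3")]
    expect_gte(attr(predict(fit, shuf), "rmse"), base_rmse)
  }
})

test_that("the pooled polynomial model contains a cubic truth", {
  n <- 400
  tb <- withr::with_seed(12, {
    c1 <- runif(n); c2 <- runif(n); c3 <- runif(n)
    tibble::tibble(t = seq_len(n) - 1, y = c1^3, c1 = c1, c2 = c2, c3 = c3)
  })
  fit3 <- fit_poly_global(tb, degree = 3)
  expect_equal(fit3$r_squared, 1, tolerance = 1e-6)
  expect_lt(fit3$rmse, 1e-4)
  fit1 <- fit_poly_global(tb, degree = 1)
  expect_gt(fit1$rmse, fit3$rmse)
  g <- glance(fit3)
  expect_equal(g$df, 19)
  expect_true(g$p.value < 1e-10)
})

test_that("degrees of freedom follow (terms, n - terms - 1)", {
  n <- 6064
  tb <- withr::with_seed(13, tibble::tibble(
    t = seq_len(n) - 1, y = rnorm(n), c1 = runif(n), c2 = runif(n), c3 = runif(n)))
  fit <- fit_poly_global(tb, degree = 1)
  expect_equal(fit$df, c(3, 6060))
  expect_error(fit_poly_global(tb[1:15, ], degree = 3), "must exceed")
})

test_that("the SVR estimator runs on the same expanded terms", {
  tb <- withr::with_seed(14, {
    c1 <- runif(200); c2 <- runif(200); c3 <- runif(200)
    tibble::tibble(t = seq_len(200) - 1,
                   y = 40 + 30 * c1^2 - 10 * c2 + rnorm(200, 0, 0.5),
                   c1 = c1, c2 = c2, c3 = c3)
  })
  fit <- fit_poly_global(tb, degree = 2, method = "svr")
  expect_true(is.finite(fit$rmse))
  expect_gt(fit$r_squared, 0.9)
})

test_that("VIF equals the brute-force 1/(1-R2) oracle", {
  X <- withr::with_seed(15, {
    z <- rnorm(200)
    cbind(a = z + rnorm(200), b = z + rnorm(200), c = z + rnorm(200))
  })
  vr <- vif_report(X)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(vr$vif[j], 1 / (1 - r2), tolerance = 1e-9)
  }
  # agreement with the standard regression-package implementation
  y <- withr::with_seed(16, rnorm(200))
  d <- data.frame(y = y, X)
  expect_equal(unname(car::vif(lm(y ~ a + b + c, d))), vr$vif,
               tolerance = 1e-9)
})

test_that("orthogonal and collinear designs give VIF 1 and infinity", {
  Xo <- cbind(a = rep(c(1, -1), 50), b = rep(c(1, 1, -1, -1), 25),
              c = rep(c(1, -1, -1, 1), 25))
  expect_equal(vif_report(Xo)$vif, rep(1, 3))
  Xc <- withr::with_seed(17, cbind(a = runif(50), b = runif(50)))
  Xc <- cbind(Xc, c = Xc[, "a"] + Xc[, "b"])
  expect_warning(vr2 <- vif_report(Xc), "collinear")
  expect_true(all(is.infinite(vr2$vif)))
})

test_that("cohort summaries use means and n-1 standard deviations", {
  co <- example_cohort()
  s <- summarize_cohort(co)
  expect_setequal(s$variable, c("age", "weight", "height"))
  a <- co$age
  expect_equal(s$mean[s$variable == "age"], mean(a))
  expect_equal(s$sd[s$variable == "age"], sqrt(sum((a - mean(a))^2) / (length(a) - 1)))
  expect_error(summarize_cohort(co[1, ]), "at least 2")
  expect_equal(summarize_cohort(tibble::tibble(age = c(30, 30)))$sd, 0)
})
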