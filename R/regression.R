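#' Heart rate as percent of age-predicted maximum
#'
#' `maxHR% = HR * 100 / (220 - age)` — the dependent variable of all the
#' package's regression models. (The exercise protocol's termination ceiling
#' uses the different estimator `208 - 0.7 * age`; see [ramp_ceiling()].)
#'
#' @param hr Heart rate in bpm (> 0), vectorized.
#' @param age Age in years (< 220).
#' @return maxHR% on the percent scale.
#' @export
max_hr_percent <- function(hr, age) {
  if (any(age >= 220)) abort("`age` must be < 220.")
  if (any(hr <= 0)) abort("`hr` must be > 0.")
  hr * 100 / (220 - age)
}

# MacKinnon (1994, 2010) response-surface p-value for the ADF tau statistic,
# constant-only regression, one series
mackinnon_p_const <- function(stat) {
  if (!is.finite(stat)) return(NA_real_)
  if (stat > 2.74) return(1)
  if (stat < -18.83) return(0)
  if (stat <= -1.61) {
    co <- c(2.1659, 1.4412, 0.038269)
    pnorm(co[1] + co[2] * stat + co[3] * stat^2)
  } else {
    co <- c(1.7339, 0.93202, -0.12745, -0.010368)
    pnorm(co[1] + co[2] * stat + co[3] * stat^2 + co[4] * stat^3)
  }
}

#' Augmented Dickey-Fuller stationarity test
#'
#' Dickey-Fuller regression with a constant,
#' `diff(y)_t ~ 1 + y_(t-1) + diff(y)_(t-1..t-p)`, with the augmentation
#' order `p` selected by AIC over `0..max_lag` on a common sample
#' (default `max_lag = floor(12 * (n/100)^0.25)`). The statistic is the
#' t-ratio of the `y_(t-1)` coefficient; p-values use the MacKinnon
#' response-surface approximation. The unit-root null is rejected
#' (`stationary = TRUE`) when `p < alpha`. A constant series is reported as
#' degenerate and stationary.
#'
#' @param x Numeric series, length >= 10.
#' @param alpha Significance level (default 0.05).
#' @param max_lag Maximum augmentation order; `NULL` for the default rule.
#' @return One-row tibble: `statistic`, `p_value`, `lag`, `stationary`,
#'   `note`.
#' @export
adf_test <- function(x, alpha = 0.05, max_lag = NULL) {
  n <- length(x)
  if (n < 10L) abort("ADF test needs at least 10 observations.")
  if (sd(x) == 0) {
    return(tibble(statistic = NA_real_, p_value = 0, lag = 0L,
                  stationary = TRUE,
                  note = "constant series (degenerate); treated as stationary"))
  }
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  max_lag <- min(max_lag, n %/% 2 - 2L)
  dx <- diff(x)
  N <- length(dx)
  fit_p <- function(p, start) {
    i <- start:N
    X <- cbind(1, x[i])
    if (p > 0) for (k in seq_len(p)) X <- cbind(X, dx[i - k])
    f <- stats::lm.fit(X, dx[i])
    list(fit = f, n_eff = length(i), k = ncol(X))
  }
  start_common <- max_lag + 1L
  aics <- vapply(0:max_lag, function(p) {
    r <- fit_p(p, start_common)
    rss <- sum(r$fit$residuals^2)
    r$n_eff * log(rss / r$n_eff) + 2 * r$k
  }, numeric(1))
  p_star <- (0:max_lag)[which.min(aics)]
  r <- fit_p(p_star, p_star + 1L)
  res <- r$fit$residuals
  dof <- r$n_eff - r$k
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(chol(crossprod(cbind(1, x[(p_star + 1L):N],
    if (p_star > 0) vapply(seq_len(p_star), function(k) dx[((p_star + 1L):N) - k],
                           numeric(r$n_eff)) else NULL))))
  se_rho <- sqrt(sigma2 * XtXinv[2, 2])
  stat <- unname(r$fit$coefficients[2] / se_rho)
  p_value <- mackinnon_p_const(stat)
  tibble(statistic = stat, p_value = p_value, lag = p_star,
         stationary = p_value < alpha, note = NA_character_)
}

# pick out the predictor channel columns of a design table
design_channels <- function(table) {
  setdiff(names(table), c("t", "y", "participant", "age", "maxhr_pct"))
}

#' Fit the lag-1 multivariate autoregression
#'
#' Ordinary least squares of `y(t)` on an intercept, its own previous value
#' `y(t-1)`, and the three lagged color channels `CR(t-1)`, over
#' `t = 2..n`:
#' `y(t) = a1 + w1 * y(t-1) + sum_n wn * CRn(t-1) + e(t)`.
#'
#' @param table Design tibble: columns `t`, `y` (maxHR%), three min-max
#'   normalized channel columns, optionally `participant` and `age`.
#' @return An object of class `ar1_fit` with components `a1`, `w1`, `wn`
#'   (named channel coefficients), `residuals`, `rmse`, `channels`, `n`,
#'   and the underlying `lm` fit. Rank-deficient designs are rejected with
#'   the offending column named.
#' @export
fit_ar1 <- function(table) {
  chans <- design_channels(table)
  if (length(chans) < 1L) abort("design table has no predictor channels.")
  n <- nrow(table)
  if (n < 10L) abort("need at least 10 rows to fit a lag-1 autoregression.")
  y <- table$y
  dat <- data.frame(.y = y[-1], .ylag = y[-n],
                    as.data.frame(table[-n, chans, drop = FALSE]))
  M <- as.matrix(cbind(1, dat[, -1, drop = FALSE]))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- setdiff(colnames(M), colnames(M)[qrM$pivot[seq_len(qrM$rank)]])
    abort(sprintf("rank-deficient design: column(s) %s are collinear with the others.",
                  paste(dropped, collapse = ", ")),
          class = "facehr_rank_deficient")
  }
  fit <- lm(.y ~ ., data = dat)
  cf <- coef(fit)
  res <- stats::residuals(fit)
  structure(list(
    a1 = unname(cf[1]), w1 = unname(cf[2]),
    wn = setNames(unname(cf[-(1:2)]), chans),
    residuals = unname(res),
    rmse = sqrt(mean(res^2)),
    channels = chans, n = n, lm = fit
  ), class = "ar1_fit")
}

#' @export
print.ar1_fit <- function(x, ...) {
  cat(sprintf("<ar1_fit: n = %d, rmse = %.4g>\n", x$n, x$rmse))
  cat("  a1 =", format(x$a1, digits = 4), " w1 =", format(x$w1, digits = 4), "\n")
  cat("  wn:", paste(sprintf("%s = %.4g", names(x$wn), x$wn), collapse = ", "), "\n")
  invisible(x)
}

#' One-step-ahead predictions from a lag-1 autoregression
#'
#' Predicts `y(t)` from the observed `y(t-1)` and lagged channels of
#' `newdata`, for `t = 2..n`. The prediction RMSE is attached as the
#' `"rmse"` attribute.
#'
#' @param object An [fit_ar1()] result.
#' @param newdata Design tibble with the same channel names.
#' @param ... Unused.
#' @return Tibble with columns `t`, `y`, `.fitted`.
#' @export
predict.ar1_fit <- function(object, newdata, ...) {
  chans <- design_channels(newdata)
  if (!identical(sort(chans), sort(object$channels))) {
    abort(sprintf("channel mismatch: fit has {%s}, newdata has {%s}.",
                  paste(object$channels, collapse = ", "),
                  paste(chans, collapse = ", ")))
  }
  n <- nrow(newdata)
  y <- newdata$y
  X <- as.matrix(newdata[-n, object$channels, drop = FALSE])
  pred <- object$a1 + object$w1 * y[-n] + as.numeric(X %*% object$wn)
  out <- tibble(t = newdata$t[-1], y = y[-1], .fitted = pred)
  attr(out, "rmse") <- sqrt(mean((out$y - out$.fitted)^2))
  out
}

#' @exportS3Method generics::tidy
tidy.ar1_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(term = c("a1", "w1", x$channels),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @exportS3Method generics::glance
glance.ar1_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble(rmse = x$rmse, r.squared = s$r.squared, nobs = x$n - 1L)
}

# all monomials of total degree 1..degree in the channel columns
poly_expand <- function(X, degree) {
  args <- c(lapply(seq_len(ncol(X)), function(j) X[, j]),
            list(degree = degree, raw = TRUE))
  out <- do.call(stats::polym, args)
  colnames(out) <- vapply(strsplit(colnames(out), ".", fixed = TRUE),
                          function(d) {
                            pow <- as.integer(d)
                            paste0(colnames(X)[pow > 0], "^", pow[pow > 0],
                                   collapse = "*")
                          }, character(1))
  out
}

#' Pooled polynomial regression of maxHR% on the color channels
#'
#' Rows from all participants are pooled and the three channels expanded to
#' every monomial of total degree up to `degree` (19 terms at degree 3).
#' The default estimator is ridge-regularized least squares (deterministic;
#' `lambda` is the ridge penalty on standardized terms); an
#' epsilon-insensitive support-vector loss on the same expanded terms is
#' available with `method = "svr"`. Metrics are computed on the pooled
#' in-sample predictions: RMSE, R-squared, and the overall F statistic with
#' `df = (p_terms, n - p_terms - 1)`.
#'
#' @param tables A design tibble or list of design tibbles (one per
#'   participant) with identical channel names.
#' @param degree Maximum total polynomial degree (default 3).
#' @param method `"ridge"` (default) or `"svr"`.
#' @param lambda Ridge penalty (default 1e-6).
#' @param epsilon,cost SVR loss parameters (defaults 0.1 and 1).
#' @return An object of class `poly_fit`.
#' @export
fit_poly_global <- function(tables, degree = 3, method = c("ridge", "svr"),
                            lambda = 1e-6, epsilon = 0.1, cost = 1) {
  method <- match.arg(method)
  if (is.data.frame(tables)) tables <- list(tables)
  chans <- design_channels(tables[[1]])
  for (tb in tables) {
    if (!identical(design_channels(tb), chans)) {
      abort("all design tables must share the same channel columns.")
    }
  }
  pooled <- dplyr::bind_rows(tables)
  X0 <- as.matrix(pooled[, chans, drop = FALSE])
  y <- pooled$y
  X <- poly_expand(X0, degree)
  p <- ncol(X)
  n <- nrow(X)
  if (n <= p + 1L) {
    abort(sprintf("pooled n (%d) must exceed the %d expanded terms + 1.", n, p))
  }
  if (method == "ridge") {
    mu <- colMeans(X); sdev <- apply(X, 2, sd)
    sdev[sdev == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    yc <- y - mean(y)
    beta_s <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yc))
    beta <- as.numeric(beta_s) / sdev
    intercept <- mean(y) - sum(mu * beta)
    fitted <- intercept + as.numeric(X %*% beta)
    coefs <- setNames(c(intercept, beta), c("(Intercept)", colnames(X)))
    svm_fit <- NULL
  } else {
    svm_fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                          kernel = "linear", cost = cost, epsilon = epsilon,
                          scale = TRUE)
    fitted <- as.numeric(stats::predict(svm_fit, X))
    coefs <- NULL
  }
  res <- y - fitted
  sse <- sum(res^2); sst <- sum((y - mean(y))^2)
  r2 <- max(0, min(1, 1 - sse / sst))
  df2 <- n - p - 1L
  fstat <- (r2 / p) / ((1 - r2) / df2)
  structure(list(
    method = method, degree = degree, channels = chans,
    coefficients = coefs, svm = svm_fit,
    fitted = fitted, y = y, n = n,
    rmse = sqrt(mean(res^2)), r_squared = r2,
    f_stat = fstat, df = c(p, df2),
    p_value = pf(fstat, p, df2, lower.tail = FALSE)
  ), class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("<poly_fit (%s, degree %d): n = %d, rmse = %.4g, R2 = %.3f, F(%d,%d) = %.4g>\n",
              x$method, x$degree, x$n, x$rmse, x$r_squared, x$df[1], x$df[2], x$f_stat))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.poly_fit <- function(x, ...) {
  if (is.null(x$coefficients)) {
    warn("per-term coefficients are not available for the SVR estimator.")
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.poly_fit <- function(x, ...) {
  tibble(rmse = x$rmse, r.squared = x$r_squared, statistic = x$f_stat,
         df = x$df[1], df.residual = x$df[2], p.value = x$p_value,
         nobs = x$n)
}

#' Variance inflation factors of the channel predictors
#'
#' For each channel `j`, `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from the
#' regression of channel `j` on the other channels with intercept. Perfect
#' collinearity yields an infinite VIF with a warning. When the dependent
#' variable `y` is supplied, the slope p-value of the univariate regression
#' `y ~ channel_j` is reported alongside.
#'
#' @param predictors Tibble or matrix of channel columns (n > 4 rows).
#' @param y Optional dependent variable for univariate p-values.
#' @return Tibble with columns `channel`, `vif`, and `p_value` (NA when `y`
#'   is absent).
#' @export
vif_report <- function(predictors, y = NULL) {
  X <- as.matrix(predictors)
  if (nrow(X) <= 4L) abort("need n > 4 observations for a VIF report.")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    if (sd(X[, j]) == 0) return(Inf)   # constant column: collinear with intercept
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    # suppressed: summary.lm warns separately on exact fits, which the
    # explicit infinite-VIF branch below already reports
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vifs))) {
    warn(sprintf("perfectly collinear predictor(s): %s (VIF infinite).",
                 paste(colnames(X)[is.infinite(vifs)], collapse = ", ")))
  }
  pvals <- rep(NA_real_, ncol(X))
  if (!is.null(y)) {
    pvals <- vapply(seq_len(ncol(X)), function(j) {
      if (sd(X[, j]) == 0) return(NA_real_)
      summary(lm(y ~ X[, j]))$coefficients[2, 4]
    }, numeric(1))
  }
  tibble(channel = colnames(X), vif = vifs, p_value = pvals)
}

#' Cohort summary statistics
#'
#' Arithmetic means and sample (n-1 denominator) standard deviations of the
#' cohort's numeric descriptors.
#'
#' @param cohort Tibble of participant records (e.g. [example_cohort()]).
#' @param vars Columns to summarise; defaults to the numeric descriptors
#'   present among age, weight, height.
#' @return Tibble with columns `variable`, `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(cohort,
                             vars = intersect(c("age", "weight", "height"),
                                              names(cohort))) {
  if (nrow(cohort) < 2L) abort("need at least 2 participants to summarise.")
  purrr::map_dfr(vars, function(v) {
    x <- cohort[[v]]
    tibble(variable = v, mean = mean(x), sd = sd(x), n = length(x))
  })
}
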