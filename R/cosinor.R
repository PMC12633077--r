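#' Linearize clock time into cosine/sine regressors
#'
#' The single-cosinor model \eqn{Y(t) = M + A\cos(2\pi t/\tau + \phi)} is
#' linear in the regressors \eqn{x = \cos(2\pi t/\tau)} and
#' \eqn{z = \sin(2\pi t/\tau)}, since
#' \eqn{A\cos(2\pi t/\tau + \phi) = \beta x + \gamma z} with
#' \eqn{\beta = A\cos\phi} and \eqn{\gamma = -A\sin\phi}.
#'
#' @param time_h Numeric vector of clock times in hours.
#' @param period_h Rhythm period \eqn{\tau} in hours (default 24).
#' @return A tibble with columns `x` and `z`, both in \[-1, 1\].
#' @examples
#' linearize_time(c(0, 6, 12, 18), 24)
#' @export
linearize_time <- function(time_h, period_h = 24) {
  if (!is.numeric(period_h) || length(period_h) != 1 ||
      !is.finite(period_h) || period_h <= 0) {
    stop("`period_h` must be a single finite positive number.", call. = FALSE)
  }
  if (!is.numeric(time_h) || any(!is.finite(time_h))) {
    stop("`time_h` must be numeric and finite.", call. = FALSE)
  }
  theta <- 2 * pi * time_h / period_h
  tibble::tibble(x = cos(theta), z = sin(theta))
}

#' Fit a single cosinor model to cross-sectional time-course data
#'
#' Ordinary least squares of the measured value on
#' \eqn{(1, \cos(2\pi t/\tau), \sin(2\pi t/\tau))} at a fixed period
#' \eqn{\tau}. The intercept is the MESOR (midline estimating statistic of
#' rhythm); the two slope coefficients \eqn{(\beta, \gamma)} are
#' delinearized into amplitude \eqn{A = \sqrt{\beta^2+\gamma^2}} and
#' acrophase \eqn{\phi = \mathrm{atan2}(-\gamma, \beta)}, reported as the
#' clock time of the fitted peak in hours on \[0, \eqn{\tau}).
#' Standard errors for amplitude and acrophase come from the delta method
#' applied to the OLS covariance of \eqn{(M, \beta, \gamma)}.
#'
#' Each subject contributes a single observation (cross-sectional design);
#' the rhythm is inferred across subjects binned by timepoint.
#'
#' @param data A data frame with one row per observation.
#' @param period Fixed period \eqn{\tau} in hours; default 24 h.
#' @param time,value Columns of `data` holding time-of-day in hours and the
#'   measurement (tidy-eval; defaults `time_h` and `value`).
#' @return An object of class `cosinor_fit`: a list carrying the point
#'   estimates (`mesor`, `amplitude`, `acrophase_h`, `beta`, `gamma`,
#'   `phi`), their standard errors, the 3x3 coefficient covariance `cov3`,
#'   the fit decomposition (`rss`, `mss`, `tss`, `sigma2`, `r2`), `n`,
#'   `period_h`, and `amplitude_defined` (FALSE when the fitted amplitude
#'   is numerically zero, in which case acrophase fields are `NA`).
#' @seealso [zero_amplitude_test()], [compare_cosinor()],
#'   [tidy.cosinor_fit()], [autoplot.cosinor_fit()]
#' @examples
#' cohort <- simulate_cohort(
#'   cohort_params("gene", "WT", mesor = 10, amplitude = 3,
#'                 acrophase_h = 19.3, noise_sd = 0.5),
#'   n_per_cell = 5, seed = 1
#' )
#' fit <- fit_cosinor(cohort)
#' fit
#' tidy(fit)
#' @export
fit_cosinor <- function(data, period = 24, time = time_h, value = value) {
  t_h <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  if (!is.numeric(period) || length(period) != 1 ||
      !is.finite(period) || period <= 0) {
    stop("`period` must be a single finite positive number.", call. = FALSE)
  }
  if (any(!is.finite(t_h)) || any(!is.finite(y))) {
    stop("times and values must be finite (drop missing rows first).",
         call. = FALSE)
  }
  n <- length(y)
  if (n < 4) {
    stop("insufficient data: a cosinor fit needs n >= 4 observations, got ",
         n, ".", call. = FALSE)
  }
  n_times <- dplyr::n_distinct(round(t_h %% period, 9))
  if (n_times < 3) {
    stop("rank-deficient design: need >= 3 distinct timepoints modulo the ",
         "period, got ", n_times, ".", call. = FALSE)
  }
  reg <- linearize_time(t_h, period)
  X <- cbind(1, reg$x, reg$z)
  if (qr(X)$rank < 3L) {
    stop("rank-deficient design: cosine/sine regressors are collinear at ",
         "these timepoints.", call. = FALSE)
  }
  ols <- stats::lm.fit(X, y)
  cf <- ols$coefficients
  mesor <- cf[[1]]; beta <- cf[[2]]; gamma <- cf[[3]]

  rss <- sum(ols$residuals^2)
  tss <- sum((y - mean(y))^2)
  mss <- max(tss - rss, 0)
  sigma2 <- rss / (n - 3)
  xtx_inv <- chol2inv(qr.R(qr(X)))
  cov3 <- sigma2 * xtx_inv
  dimnames(cov3) <- list(c("mesor", "beta", "gamma"),
                         c("mesor", "beta", "gamma"))

  amplitude <- sqrt(beta^2 + gamma^2)
  amplitude_defined <- amplitude >= 1e-10 * max(1, abs(mesor))
  if (amplitude_defined) {
    phi <- atan2(-gamma, beta)
    acrophase_h <- (-phi * period / (2 * pi)) %% period
    g_amp <- c(0, beta, gamma) / amplitude
    amplitude_se <- sqrt(drop(g_amp %*% cov3 %*% g_amp))
    g_phi <- c(0, gamma, -beta) / amplitude^2
    acrophase_se_h <- sqrt(drop(g_phi %*% cov3 %*% g_phi)) * period / (2 * pi)
  } else {
    phi <- NA_real_
    acrophase_h <- NA_real_
    amplitude_se <- sqrt(cov3[2, 2] + cov3[3, 3]) / sqrt(2)
    acrophase_se_h <- NA_real_
  }

  structure(
    list(
      period_h = period, n = n,
      mesor = mesor, mesor_se = sqrt(cov3[1, 1]),
      amplitude = amplitude, amplitude_se = amplitude_se,
      acrophase_h = acrophase_h, acrophase_se_h = acrophase_se_h,
      beta = beta, gamma = gamma, phi = phi,
      cov3 = cov3, sigma2 = sigma2,
      rss = rss, mss = mss, tss = tss,
      r2 = if (tss > 0) mss / tss else 0,
      amplitude_defined = amplitude_defined,
      data = tibble::tibble(time_h = t_h, value = y)
    ),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Single cosinor fit (period ", format(x$period_h), " h, n = ", x$n,
      ")\n", sep = "")
  est <- c(x$mesor, x$amplitude, x$acrophase_h)
  se <- c(x$mesor_se, x$amplitude_se, x$acrophase_se_h)
  lab <- c("MESOR", "Amplitude", "Acrophase (h)")
  for (i in seq_along(lab)) {
    cat(sprintf("  %-13s %10.4g +/- %.4g\n", lab[i], est[i], se[i]))
  }
  if (!x$amplitude_defined) {
    cat("  amplitude numerically zero; acrophase undefined\n")
  }
  zt <- zero_amplitude_test(x)
  cat(sprintf("  R^2 = %.4f; zero-amplitude F(%g, %g) = %.4g, p = %.3g\n",
              x$r2, zt$df1, zt$df2, zt$statistic, zt$p))
  invisible(x)
}

#' Predicted cosinor value at given clock times
#'
#' Evaluates \eqn{M + A\cos(2\pi t/\tau + \phi)} for a fitted cosinor.
#' The maximum \eqn{M + A} is attained at the acrophase.
#'
#' @param object A [fit_cosinor()] object.
#' @param time_h Clock times in hours.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.cosinor_fit <- function(object, time_h, ...) {
  if (any(!is.finite(time_h))) {
    stop("`time_h` must be finite.", call. = FALSE)
  }
  if (!object$amplitude_defined) {
    return(rep(object$mesor, length(time_h)))
  }
  object$mesor +
    object$amplitude * cos(2 * pi * time_h / object$period_h + object$phi)
}

#' Zero-amplitude F-test for rhythm detection
#'
#' Tests whether the fitted cosine explains any variance beyond a flat
#' mean: \eqn{F = (\mathrm{MSS}/2) / (\mathrm{RSS}/(n-3))}, referred to
#' \eqn{F(2, n-3)}; equivalently \eqn{F = (R^2/2)/((1-R^2)/(n-3))}. A small
#' p-value rejects the zero-amplitude (no rhythm) null.
#'
#' @param fit A [fit_cosinor()] object.
#' @return A one-row tibble with `kind = "zero_amplitude"`, `statistic`,
#'   `df1`, `df2`, `p` and `note`. Perfect fits (`rss == 0` with nonzero
#'   model sum of squares) return `statistic = Inf`, `p = 0`,
#'   `note = "perfect_fit"`.
#' @export
zero_amplitude_test <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  df1 <- 2
  df2 <- fit$n - 3
  scale <- max(fit$tss, 1)
  if (fit$mss <= 1e-12 * scale) {
    # flat series: nothing explained by the cosine
    return(test_result("zero_amplitude", 0, df1, df2, 1))
  }
  if (fit$rss <= 1e-12 * scale) {
    return(test_result("zero_amplitude", Inf, df1, df2, 0, "perfect_fit"))
  }
  f <- (fit$mss / df1) / (fit$rss / df2)
  test_result("zero_amplitude", f, df1, df2,
              stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Common one-row result tibble shared by all tests in the package.
test_result <- function(kind, statistic, df1, df2, p, note = NA_character_) {
  tibble::tibble(kind = kind, statistic = statistic,
                 df1 = df1, df2 = df2, p = p, note = note)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cosinor fit into one row per rhythm parameter
#'
#' @param x A [fit_cosinor()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error` covering
#'   the rhythm parameters (mesor, amplitude, acrophase_h) and the
#'   linearized coefficients (beta, gamma).
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase_h", "beta", "gamma"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h, x$beta, x$gamma),
    std.error = c(x$mesor_se, x$amplitude_se, x$acrophase_se_h,
                  sqrt(x$cov3[2, 2]), sqrt(x$cov3[3, 3]))
  )
}

#' One-row fit summary of a cosinor model
#'
#' @param x A [fit_cosinor()] object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `period_h`, `r.squared`, `sigma2`,
#'   `rss`, `mss`, and the zero-amplitude test (`statistic`, `df1`, `df2`,
#'   `p.value`).
#' @export
glance.cosinor_fit <- function(x, ...) {
  zt <- zero_amplitude_test(x)
  tibble::tibble(
    n = x$n, period_h = x$period_h, r.squared = x$r2, sigma2 = x$sigma2,
    rss = x$rss, mss = x$mss,
    statistic = zt$statistic, df1 = zt$df1, df2 = zt$df2, p.value = zt$p
  )
}
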