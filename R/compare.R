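#' Signed circular difference between two clock times
#'
#' Difference `a1 - a2` wrapped onto `(-period/2, period/2]`, so that
#' acrophases either side of midnight compare by their short arc. A
#' difference of exactly half a period maps to `+period/2`.
#'
#' @param a1,a2 Clock times in hours.
#' @param period_h Period in hours (default 24).
#' @return Signed difference in hours.
#' @examples
#' circular_diff_h(23.5, 0.5)   # -1, across midnight
#' circular_diff_h(0, 12)       # +12, antipode convention
#' @export
circular_diff_h <- function(a1, a2, period_h = 24) {
  if (!is.numeric(period_h) || length(period_h) != 1 ||
      !is.finite(period_h) || period_h <= 0) {
    stop("`period_h` must be a single finite positive number.", call. = FALSE)
  }
  d <- (a1 - a2) %% period_h
  ifelse(d > period_h / 2, d - period_h, d)
}

#' Compare rhythm parameters between two cosinor fits
#'
#' Wald-type F-ratios for the difference in MESOR, amplitude and acrophase
#' between two independently fitted groups: for each parameter
#' \eqn{F = (\hat\theta_1-\hat\theta_2)^2 / (SE_1^2 + SE_2^2)}, referred to
#' \eqn{F(1, n_1+n_2-6)} (six coefficients estimated across the two fits).
#' The acrophase difference is taken on the circle via [circular_diff_h()];
#' if either group's amplitude is numerically zero its acrophase is
#' undefined and the acrophase comparison returns a flagged non-result
#' rather than propagating `NaN`.
#'
#' @param fit1,fit2 [fit_cosinor()] objects sharing the same period.
#' @return A three-row tibble (`kind` = `mesor`, `amplitude`, `acrophase`)
#'   with columns `estimate` (group 1 minus group 2), `statistic`, `df1`,
#'   `df2`, `p`, `note`.
#' @examples
#' params <- dplyr::bind_rows(
#'   cohort_params("g", "WT", 10, 3, 19.3, noise_sd = 1),
#'   cohort_params("g", "KO", 10, 3, 13.3, noise_sd = 1)
#' )
#' cohort <- simulate_cohort(params, n_per_cell = 5, seed = 7)
#' fits <- lapply(split(cohort, cohort$group), fit_cosinor)
#' compare_cosinor(fits$WT, fits$KO)
#' @export
compare_cosinor <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "cosinor_fit"), inherits(fit2, "cosinor_fit"))
  if (!isTRUE(all.equal(fit1$period_h, fit2$period_h))) {
    stop("fits have different periods (", fit1$period_h, " vs ",
         fit2$period_h, " h).", call. = FALSE)
  }
  df2 <- fit1$n + fit2$n - 6

  wald <- function(kind, est, v) {
    f <- est^2 / v
    res <- test_result(kind, f, 1, df2,
                       stats::pf(f, 1, df2, lower.tail = FALSE))
    res$estimate <- est
    res
  }

  mesor <- wald("mesor", fit1$mesor - fit2$mesor,
                fit1$mesor_se^2 + fit2$mesor_se^2)
  amplitude <- wald("amplitude", fit1$amplitude - fit2$amplitude,
                    fit1$amplitude_se^2 + fit2$amplitude_se^2)
  if (fit1$amplitude_defined && fit2$amplitude_defined) {
    acro <- wald("acrophase",
                 circular_diff_h(fit1$acrophase_h, fit2$acrophase_h,
                                 fit1$period_h),
                 fit1$acrophase_se_h^2 + fit2$acrophase_se_h^2)
  } else {
    acro <- test_result("acrophase", NA_real_, 1, df2, NA_real_,
                        "amplitude_undefined")
    acro$estimate <- NA_real_
  }
  dplyr::bind_rows(mesor, amplitude, acro)[
    , c("kind", "estimate", "statistic", "df1", "df2", "p", "note")]
}

#' Population-mean cosinor from a set of fits
#'
#' Averages the linearized coefficients \eqn{(M, \beta, \gamma)} across
#' contributing fits and delinearizes the mean vector into a population
#' amplitude and acrophase. Averaging happens in the \eqn{(\beta,\gamma)}
#' plane (vector averaging), never on acrophase angles directly, so two
#' rhythms peaking at 1 h and 23 h average to a peak at 0 h, not 12 h.
#' Standard errors come from the empirical covariance of the contributing
#' coefficient vectors (delta method for amplitude and acrophase) and are
#' defined only for two or more fits.
#'
#' @param fits A list of [fit_cosinor()] objects sharing a period.
#' @return An object of class `population_cosinor` with fields `k`,
#'   `period_h`, `mesor`, `beta`, `gamma`, `amplitude`, `acrophase_h`, and
#'   `mesor_se`, `amplitude_se`, `acrophase_se_h` (`NA` when `k < 2`).
#' @export
population_cosinor <- function(fits) {
  if (length(fits) < 1) {
    stop("`fits` must contain at least one cosinor fit.", call. = FALSE)
  }
  ok <- vapply(fits, inherits, logical(1), what = "cosinor_fit")
  if (!all(ok)) stop("all elements must be cosinor fits.", call. = FALSE)
  periods <- vapply(fits, `[[`, numeric(1), "period_h")
  if (diff(range(periods)) > 1e-9) {
    stop("fits have different periods.", call. = FALSE)
  }
  k <- length(fits)
  B <- t(vapply(fits, function(f) c(f$mesor, f$beta, f$gamma), numeric(3)))
  m <- colMeans(B)
  mesor <- m[1]; beta <- m[2]; gamma <- m[3]
  amplitude <- sqrt(beta^2 + gamma^2)
  period <- periods[1]
  amplitude_defined <- amplitude >= 1e-10 * max(1, abs(mesor))
  phi <- if (amplitude_defined) atan2(-gamma, beta) else NA_real_
  acrophase_h <- if (amplitude_defined) {
    (-phi * period / (2 * pi)) %% period
  } else NA_real_

  mesor_se <- amplitude_se <- acrophase_se_h <- NA_real_
  if (k >= 2) {
    S <- stats::cov(B) / k  # covariance of the mean vector
    mesor_se <- sqrt(S[1, 1])
    if (amplitude_defined) {
      g_amp <- c(0, beta, gamma) / amplitude
      amplitude_se <- sqrt(drop(g_amp %*% S %*% g_amp))
      g_phi <- c(0, gamma, -beta) / amplitude^2
      acrophase_se_h <- sqrt(drop(g_phi %*% S %*% g_phi)) * period / (2 * pi)
    }
  }
  structure(
    list(k = k, period_h = period, mesor = mesor, beta = beta, gamma = gamma,
         amplitude = amplitude, acrophase_h = acrophase_h, phi = phi,
         mesor_se = mesor_se, amplitude_se = amplitude_se,
         acrophase_se_h = acrophase_se_h,
         amplitude_defined = amplitude_defined),
    class = "population_cosinor"
  )
}

#' @export
print.population_cosinor <- function(x, ...) {
  cat("Population-mean cosinor over", x$k, "fits (period",
      format(x$period_h), "h)\n")
  cat(sprintf("  MESOR %.4g  Amplitude %.4g  Acrophase %.4g h\n",
              x$mesor, x$amplitude, x$acrophase_h))
  invisible(x)
}

#' @rdname population_cosinor
#' @param x A `population_cosinor` object.
#' @param ... Unused.
#' @export
tidy.population_cosinor <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase_h"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h),
    std.error = c(x$mesor_se, x$amplitude_se, x$acrophase_se_h)
  )
}

#' Within-timepoint two-sample Student's t-test
#'
#' Pooled-variance two-sided Student's t-test between the two groups'
#' values at one timepoint (Welch available via `var_equal = FALSE`).
#' Degenerate zero-variance inputs are resolved rather than erroring:
#' equal means give `p = 1`; unequal means give `p = 0` flagged
#' `"degenerate"`.
#'
#' @param values1,values2 Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (classical Student's t, default).
#' @return A one-row tibble with `kind = "timepoint_t"`, `statistic`
#'   (the t), `df1 = 1`, `df2` (the t degrees of freedom), `p`, `note`.
#' @export
timepoint_t_test <- function(values1, values2, var_equal = TRUE) {
  if (length(values1) < 2 || length(values2) < 2) {
    stop("each group needs >= 2 values at the timepoint.", call. = FALSE)
  }
  n1 <- length(values1); n2 <- length(values2)
  v1 <- stats::var(values1); v2 <- stats::var(values2)
  if (v1 == 0 && v2 == 0) {
    if (mean(values1) == mean(values2)) {
      return(test_result("timepoint_t", 0, 1, n1 + n2 - 2, 1))
    }
    return(test_result("timepoint_t", Inf, 1, n1 + n2 - 2, 0, "degenerate"))
  }
  tt <- stats::t.test(values1, values2, var.equal = var_equal)
  test_result("timepoint_t", unname(tt$statistic), 1,
              unname(tt$parameter), tt$p.value)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: sorted
#' ascending, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1,
#' returned in input order. `NA` entries pass through untouched and do not
#' count toward `m`.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  if (!is.numeric(pvals)) stop("`pvals` must be numeric.", call. = FALSE)
  bad <- !is.na(pvals) & (pvals < 0 | pvals > 1 | !is.finite(pvals))
  if (any(bad)) {
    stop("p-values outside [0, 1] at positions: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}
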