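# Stationarity classification: augmented Dickey-Fuller (unit-root null) and
# KPSS (level-stationarity null) tests, the differencing decision, and cohort
# percentage tables. Both tests are implemented here on the conventional
# constant-only / level specification, which is the standard choice for
# physiologic means that fluctuate around a setpoint without deterministic
# trend.

# Dickey-Fuller tau distribution quantiles, regression with constant
# (tau_mu; Fuller 1976 / MacKinnon). Rows: sample size; columns: cumulative
# probabilities. p-values are obtained by bilinear interpolation and clamped
# to [0.01, 0.99].
.adf_tau_mu <- list(
  n = c(25, 50, 100, 250, 500, Inf),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  q = rbind(
    c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60))
)

adf_p_value <- function(stat, n) {
  tab <- .adf_tau_mu
  # interpolate critical values at this sample size, then invert
  crit <- vapply(seq_along(tab$p), function(j) {
    stats::approx(tab$n[-length(tab$n)], tab$q[-nrow(tab$q), j], xout = n,
                  rule = 2)$y
  }, numeric(1))
  if (n >= 500) crit <- tab$q[nrow(tab$q), ]
  p <- stats::approx(crit, tab$p, xout = stat, rule = 2)$y
  min(0.99, max(0.01, p))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Regression of the first difference on the lagged level with a constant and
#' no deterministic trend; the augmentation lag order is chosen by AIC over
#' `0..max_lag` (default cap `floor(12 * (n/100)^(1/4))`) on a common sample,
#' then the test is refit at the selected lag. The null hypothesis is a unit
#' root; p-values come from interpolation in the Dickey-Fuller tau table for
#' the constant case and are clamped to `[0.01, 0.99]`.
#'
#' @param x Numeric series (`NA`s dropped are not allowed; supply a gap-free
#'   segment).
#' @param max_lag Maximum augmentation lag; default Schwert's rule.
#' @param alpha Rejection level (default 0.05).
#' @param min_n Minimum usable length; shorter series return an `NA` result.
#' @return List with `stat`, `p`, `reject`, `lag`, `n`, `usable`.
#' @export
adf_test <- function(x, max_lag = NULL, alpha = 0.05, min_n = 30L) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x) || n < min_n || stats::sd(x) == 0) {
    return(list(stat = NA_real_, p = NA_real_, reject = NA, lag = NA_integer_,
                n = n, usable = FALSE))
  }
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  max_lag <- max(0L, min(max_lag, n %/% 3 - 2L))
  dx <- diff(x)

  fit_at <- function(k, common_from) {
    # rows t = common_from..(n-1) of the difference series
    idx <- common_from:(n - 1L)
    y <- dx[idx]
    X <- cbind(1, x[idx])
    if (k > 0) {
      lags <- sapply(seq_len(k), function(i) dx[idx - i])
      X <- cbind(X, lags)
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    nobs <- length(y)
    list(fit = fit, rss = rss, nobs = nobs, k = k,
         aic = nobs * log(rss / nobs) + 2 * (k + 2))
  }

  common_from <- max_lag + 1L
  aics <- vapply(0:max_lag, function(k) fit_at(k, common_from)$aic, numeric(1))
  k_best <- (0:max_lag)[which.min(aics)]
  f <- fit_at(k_best, k_best + 1L)  # refit on the longest sample

  # t statistic on the lagged-level coefficient
  nobs <- f$nobs
  df_res <- nobs - (f$k + 2L)
  sigma2 <- f$rss / df_res
  X <- cbind(1, x[(f$k + 1L):(n - 1L)])
  if (f$k > 0) {
    X <- cbind(X, sapply(seq_len(f$k), function(i) dx[((f$k + 1L):(n - 1L)) - i]))
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_rho <- sqrt(sigma2 * XtXinv[2, 2])
  stat <- f$fit$coefficients[2] / se_rho
  p <- adf_p_value(stat, nobs)
  list(stat = unname(stat), p = p, reject = p < alpha, lag = k_best,
       n = n, usable = TRUE)
}

# KPSS level-stationarity critical values (eta_mu).
.kpss_level <- list(p = c(0.10, 0.05, 0.025, 0.01),
                    crit = c(0.347, 0.463, 0.574, 0.739))

#' KPSS level-stationarity test
#'
#' Null hypothesis: the series is stationary around a constant level. The
#' statistic is the scaled sum of squared partial sums of demeaned values,
#' with the long-run variance estimated by a Bartlett-kernel (Newey-West)
#' estimator at the automatic bandwidth `floor(4 * (n/100)^(1/4))`. p-values
#' interpolate the standard critical-value table and are bracketed at
#' `[0.01, 0.10]`; the rejection flag compares the statistic with the
#' `alpha = 0.05` critical value directly.
#'
#' @inheritParams adf_test
#' @param bandwidth Bartlett-kernel truncation lag; `NULL` for automatic.
#' @return List with `stat`, `p`, `reject`, `bandwidth`, `n`, `usable`.
#' @export
kpss_test <- function(x, bandwidth = NULL, alpha = 0.05, min_n = 30L) {
  x <- as.numeric(x)
  n <- length(x)
  if (anyNA(x) || n < min_n) {
    return(list(stat = NA_real_, p = NA_real_, reject = NA,
                bandwidth = NA_integer_, n = n, usable = FALSE))
  }
  e <- x - mean(x)
  if (all(e == 0)) {
    return(list(stat = 0, p = 0.10, reject = FALSE, bandwidth = 0L, n = n,
                usable = TRUE))
  }
  if (is.null(bandwidth)) bandwidth <- floor(4 * (n / 100)^0.25)
  s_t <- cumsum(e)
  lrv <- sum(e^2) / n
  if (bandwidth > 0) {
    for (l in seq_len(bandwidth)) {
      w <- 1 - l / (bandwidth + 1)
      lrv <- lrv + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  lrv <- max(lrv, .Machine$double.eps)
  stat <- sum(s_t^2) / (n^2 * lrv)
  tab <- .kpss_level
  p <- stats::approx(tab$crit, tab$p, xout = stat, rule = 2)$y
  crit_alpha <- stats::approx(tab$p, tab$crit, xout = alpha, rule = 2)$y
  list(stat = stat, p = p, reject = stat > crit_alpha,
       bandwidth = as.integer(bandwidth), n = n, usable = TRUE)
}

#' Difference a series
#'
#' Repeated first differences; `NA` propagates to both touching differences.
#' @param x Numeric series.
#' @param order 1 or 2.
#' @return Vector of length `length(x) - order`.
#' @export
difference_series <- function(x, order = 1L) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)
  if (length(x) <= order) stop("series too short to difference", call. = FALSE)
  diff(x, differences = order)
}

#' Classify a patient x signal x resolution cell
#'
#' Cohort tables label by the KPSS test alone (reject -> non-stationary,
#' retain -> stationary); the two-test agreement flag (ADF non-reject AND KPSS
#' reject) is additionally recorded as the differencing trigger. Cells that
#' fail the sufficiency check are `NA`.
#'
#' @param adf_reject,kpss_reject Logical flags (may be `NA`).
#' @param usable Did the cell pass [sufficiency_check()]?
#' @return List with `label` in `{"stationary", "non-stationary", NA}` and
#'   `agreement_nonstationary` (the differencing trigger).
#' @export
classify_stationarity <- function(adf_reject, kpss_reject, usable = TRUE) {
  if (!isTRUE(usable) || is.na(kpss_reject)) {
    return(list(label = NA_character_, agreement_nonstationary = NA))
  }
  label <- if (kpss_reject) "non-stationary" else "stationary"
  agree <- !isTRUE(adf_reject) && isTRUE(kpss_reject)
  list(label = label, agreement_nonstationary = agree)
}

#' Run both stationarity tests on a series and classify it
#'
#' @param x Gap-free numeric segment.
#' @param alpha Test level.
#' @param min_n Sufficiency threshold for both tests.
#' @return One-row data.frame with the statistics, p-values, reject flags,
#'   label and agreement flag.
#' @export
stationarity_tests <- function(x, alpha = 0.05, min_n = 30L) {
  usable <- sufficiency_check(x, min_n) && !anyNA(x)
  a <- adf_test(x, alpha = alpha, min_n = min_n)
  k <- kpss_test(x, alpha = alpha, min_n = min_n)
  cl <- classify_stationarity(a$reject, k$reject, usable && a$usable && k$usable)
  data.frame(adf_stat = a$stat, adf_p = a$p, adf_reject = a$reject,
             kpss_stat = k$stat, kpss_p = k$p, kpss_reject = k$reject,
             label = cl$label,
             agreement_nonstationary = cl$agreement_nonstationary,
             n = length(x))
}

#' Cohort stationarity percentage table
#'
#' For each signal x resolution cell, the percentage of patients labelled
#' stationary, non-stationary, and NA (denominator = cohort size), each
#' rounded to 0.1.
#'
#' @param results data.frame with columns `patient_id, signal, resolution,
#'   label`.
#' @return data.frame with columns `signal, resolution, stationary,
#'   non_stationary, na`; empty input yields an empty table.
#' @export
cohort_stationarity_table <- function(results) {
  if (!nrow(results)) {
    return(data.frame(signal = character(0), resolution = numeric(0),
                      stationary = numeric(0), non_stationary = numeric(0),
                      na = numeric(0)))
  }
  cells <- unique(results[c("signal", "resolution")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$signal == cells$signal[i] &
                     results$resolution == cells$resolution[i], ]
    n <- nrow(sub)
    lab <- sub$label
    data.frame(signal = cells$signal[i], resolution = cells$resolution[i],
               stationary = round(100 * sum(lab == "stationary", na.rm = TRUE) / n, 1),
               non_stationary = round(100 * sum(lab == "non-stationary", na.rm = TRUE) / n, 1),
               na = round(100 * sum(is.na(lab)) / n, 1))
  })
  out <- do.call(rbind, rows)
  out[order(out$signal, out$resolution), , drop = FALSE]
}
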