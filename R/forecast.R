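# One-step-ahead forecast evaluation with fixed orders: Pearson agreement and
# Bland-Altman limits of agreement.

#' Rolling one-step-ahead forecasts with fixed orders
#'
#' Fits the model once on the initial `train_fraction` of the series, then
#' advances one step at a time, appending each newly observed value to the
#' model's state WITHOUT re-estimating coefficients and emitting the
#' one-step-ahead prediction before the observation is revealed. With
#' `refit_each_step = TRUE`, coefficients are re-estimated at every step
#' (slow; provided for sensitivity analysis).
#'
#' @param x Numeric series.
#' @param order `c(p, d, q)`.
#' @param train_fraction Fraction of the series used to estimate coefficients
#'   (default 0.5).
#' @param with_constant Estimate a mean term (default only when `d == 0`).
#' @param refit_each_step Re-estimate coefficients at each step?
#' @return List with `predictions`, `observations` (both of length
#'   `n - n_train`), `n_train`, and `order`.
#' @export
rolling_one_step <- function(x, order, train_fraction = 0.5,
                             with_constant = (order[2] == 0),
                             refit_each_step = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  p <- order[1]; d <- order[2]; q <- order[3]
  k <- p + q + as.integer(with_constant) + 1L
  n_train <- floor(n * train_fraction)
  if (n_train < k + 10L) {
    stop("training window shorter than k + 10", call. = FALSE)
  }
  if (n_train >= n) stop("no test observations left", call. = FALSE)

  # Degenerate case: the d-times-differenced training data are constant
  # (e.g. a pure ramp under d = 1). ML fitting is singular there, but the
  # one-step predictor has a closed form: Delta^d xhat_t = c with c the
  # constant difference, expanded through the binomial coefficients.
  w_train <- if (d > 0) diff(x[seq_len(n_train)], differences = d)
             else x[seq_len(n_train)]
  if (stats::sd(w_train) == 0) {
    cst <- w_train[1]
    preds <- vapply((n_train + 1L):n, function(t) {
      val <- cst
      if (d > 0) for (j in seq_len(d)) {
        val <- val - (-1)^j * choose(d, j) * x[t - j]
      }
      val
    }, numeric(1))
    return(list(predictions = unname(preds),
                observations = x[(n_train + 1L):n],
                n_train = n_train, order = order))
  }

  if (refit_each_step) {
    preds <- vapply((n_train):(n - 1L), function(m) {
      fit <- suppressWarnings(stats::arima(x[seq_len(m)], order = order,
                                           include.mean = with_constant,
                                           method = "CSS-ML"))
      as.numeric(stats::predict(fit, n.ahead = 1L)$pred)
    }, numeric(1))
  } else {
    fit <- suppressWarnings(stats::arima(x[seq_len(n_train)], order = order,
                                         include.mean = with_constant,
                                         method = "CSS-ML"))
    cf <- stats::coef(fit)
    if (length(cf)) {
      # Filter the full series at the frozen coefficients: with every
      # parameter fixed, stats::arima performs no optimization and the
      # Kalman one-step-ahead prediction of x_t is x_t minus the innovation.
      refit <- suppressWarnings(stats::arima(x, order = order,
                                             include.mean = with_constant,
                                             fixed = cf,
                                             transform.pars = FALSE))
    } else {
      refit <- suppressWarnings(stats::arima(x, order = order,
                                             include.mean = FALSE))
    }
    innov <- as.numeric(stats::residuals(refit))
    preds <- (x - innov)[(n_train + 1L):n]
  }
  list(predictions = unname(preds),
       observations = x[(n_train + 1L):n],
       n_train = n_train, order = order)
}

#' Pearson agreement between forecasts and observations
#'
#' @param predictions,observations Equal-length numeric vectors (>= 3 pairs).
#' @return Pearson r, or `NA` when either input is constant.
#' @export
pearson_agreement <- function(predictions, observations) {
  if (length(predictions) != length(observations)) {
    stop("length mismatch", call. = FALSE)
  }
  ok <- !is.na(predictions) & !is.na(observations)
  if (sum(ok) < 3L) return(NA_real_)
  safe_cor(predictions[ok], observations[ok])
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `forecast - observed` throughout. The limits of
#' agreement are `mean(d) +/- 1.96 * SD(d)` with the sample (n-1) standard
#' deviation.
#'
#' @param predictions,observations Paired numeric vectors (>= 2 pairs).
#' @return List with `mean_diff`, `lower_loa`, `upper_loa`, `loa_spread`,
#'   `n`.
#' @export
bland_altman <- function(predictions, observations) {
  if (length(predictions) != length(observations)) {
    stop("length mismatch", call. = FALSE)
  }
  d <- predictions - observations
  d <- d[!is.na(d)]
  if (length(d) < 2L) {
    return(list(mean_diff = NA_real_, lower_loa = NA_real_,
                upper_loa = NA_real_, loa_spread = NA_real_, n = length(d)))
  }
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, lower_loa = m - 1.96 * s, upper_loa = m + 1.96 * s,
       loa_spread = 2 * 1.96 * s, n = length(d))
}

#' Evaluate one-step forecasting for one patient x signal
#'
#' Runs [rolling_one_step()], then computes Pearson r and the Bland-Altman
#' quantities on the same paired set.
#'
#' @inheritParams rolling_one_step
#' @param patient_id,signal Identifiers carried into the output row.
#' @return One-row data.frame: `patient_id, signal, p, d, q, pearson_r,
#'   ba_mean, ba_lower, ba_upper, loa_spread, n_forecasts`.
#' @export
evaluate_forecast <- function(x, order, train_fraction = 0.5,
                              patient_id = NA_character_,
                              signal = NA_character_, ...) {
  ro <- rolling_one_step(x, order, train_fraction, ...)
  r <- pearson_agreement(ro$predictions, ro$observations)
  ba <- bland_altman(ro$predictions, ro$observations)
  data.frame(patient_id = patient_id, signal = signal,
             p = order[1], d = order[2], q = order[3],
             pearson_r = r, ba_mean = ba$mean_diff, ba_lower = ba$lower_loa,
             ba_upper = ba$upper_loa, loa_spread = ba$loa_spread,
             n_forecasts = length(ro$predictions))
}

#' Pair per-patient Pearson r with Bland-Altman spread
#'
#' Scatter table (and optional plot) of forecast correlation against the
#' width of the limits of agreement.
#' @param evaluations data.frame of [evaluate_forecast()] rows.
#' @param plot Draw the scatter?
#' @return data.frame with `patient_id, signal, pearson_r, loa_spread`.
#' @export
correlation_vs_spread <- function(evaluations, plot = FALSE) {
  out <- evaluations[c("patient_id", "signal", "pearson_r", "loa_spread")]
  if (plot) {
    graphics::plot(out$pearson_r, out$loa_spread, xlab = "Pearson r",
                   ylab = "LoA spread (upper - lower)",
                   main = "Forecast agreement")
  }
  out
}
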