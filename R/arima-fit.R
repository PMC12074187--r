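# ARIMA grid search over (p, d, q), model selection by information criteria,
# population median optima, and residual diagnostics.
#
# The model on the differenced scale is
#   Delta^d X_t = c + sum_{i=1..p} phi_i Delta^d X_{t-i}
#                   + sum_{j=1..q} theta_j e_{t-j} + e_t,  e_t ~ N(0, sigma2).
# Fits are maximum likelihood via stats::arima (CSS-initialized ML). AIC and
# BIC are computed from the returned log-likelihood with
# k = p + q + constant + 1 (innovation variance) and n_eff = n - d.

#' Fit one ARIMA(p, d, q) cell
#'
#' Maximum-likelihood fit of a single grid cell. A failed optimization never
#' raises: it returns a record with `converged = FALSE` and infinite
#' criteria, so grid completeness stays auditable.
#'
#' @param x Numeric series (gap-free).
#' @param p,d,q Nonnegative integer orders; `d` is applied inside the fit.
#' @param with_constant Estimate a constant/mean term? Default: only when
#'   `d == 0` (a constant under differencing encodes a deterministic drift).
#' @param pre_diff Differencing already applied to `x` before the call; only
#'   recorded, so `total_d = pre_diff + d` is reported correctly.
#' @return An `arima_fit` record: list with `p, d, q, total_d, aic, bic, ll,
#'   sigma2, coef, converged, fit_seconds, n_eff` and the underlying
#'   `stats::arima` object (`fit`) when converged.
#' @export
fit_arima <- function(x, p, d, q, with_constant = (d == 0), pre_diff = 0L) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  n_eff <- length(x) - d
  k <- p + q + as.integer(with_constant) + 1L
  rec <- list(p = p, d = d, q = q, total_d = as.integer(pre_diff) + d,
              aic = Inf, bic = Inf, ll = -Inf, sigma2 = NA_real_,
              coef = NULL, converged = FALSE, fit_seconds = NA_real_,
              n_eff = n_eff, fit = NULL)
  class(rec) <- "arima_fit"
  if (n_eff <= k + 2L || anyNA(x)) return(rec)
  if (stats::sd(diff(x, differences = max(d, 1))) == 0 && stats::sd(x) == 0) {
    return(rec)  # degenerate constant series
  }
  t0 <- proc.time()[["elapsed"]]
  fit <- tryCatch(
    suppressWarnings(stats::arima(x, order = c(p, d, q),
                                  include.mean = with_constant,
                                  method = "CSS-ML")),
    error = function(e) NULL)
  rec$fit_seconds <- proc.time()[["elapsed"]] - t0
  if (is.null(fit) || !is.finite(fit$loglik)) return(rec)
  rec$ll <- fit$loglik
  rec$aic <- 2 * k - 2 * rec$ll
  rec$bic <- k * log(n_eff) - 2 * rec$ll
  rec$sigma2 <- fit$sigma2
  rec$coef <- stats::coef(fit)
  rec$converged <- TRUE
  rec$fit <- fit
  rec
}

#' Grid-search ARIMA orders for one series
#'
#' The central fitter. Runs a full (p, d, q) grid on the (optionally
#' pre-differenced) series, records AIC, BIC and log-likelihood for every
#' cell, and selects the optimum by the requested criterion (lowest AIC or
#' BIC, highest LL; ties broken toward the smaller `p + q`, then smaller
#' `p`). By default the grid spans `p` 1--10, `d` {0, 1}, `q` 0--10 and runs
#' on the first-differenced series, so the reported `total_d` lies in
#' {1, 2}. Pure MA models (`p = 0`) are unreachable under the default range;
#' widen `p_range` to include 0 if needed.
#'
#' @param x Numeric series (gap-free segment at one resolution).
#' @param p_range,q_range Integer ranges of AR / MA orders.
#' @param d_grid Differencing orders applied inside the fit.
#' @param pre_diff First-difference the series this many times before the
#'   grid (default 1, the universal pre-differencing step).
#' @param criterion `"aic"`, `"bic"` or `"ll"`.
#' @param min_n Sufficiency threshold on the pre-differenced series
#'   (default 50); shorter series raise an error.
#' @return Object of class `arima_grid`: list with `records` (one data.frame
#'   row per cell), `best` (the selected `arima_fit`), `criterion`, `series`
#'   (the pre-differenced series the grid ran on), `pre_diff`, and `call`.
#'   Supports `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' x <- simulate_arima_series(2, 1, 2, c(0.5, -0.3), c(0.4, 0.2), 1,
#'                            n = 400, seed = 7)
#' fit <- arima_grid(x, p_range = 1:3, q_range = 0:3)
#' fit
#' coef(fit)
#' @export
arima_grid <- function(x, p_range = 1:10, d_grid = c(0L, 1L), q_range = 0:10,
                       pre_diff = 1L, criterion = c("aic", "bic", "ll"),
                       min_n = 50L) {
  criterion <- match.arg(criterion)
  if (!length(p_range) || !length(d_grid) || !length(q_range)) {
    stop("empty grid", call. = FALSE)
  }
  x <- as.numeric(x)
  w <- x
  if (pre_diff > 0) w <- diff(w, differences = pre_diff)
  if (!sufficiency_check(w, min_n)) {
    stop("series too short for the grid search (needs >= ", min_n,
         " points after pre-differencing)", call. = FALSE)
  }
  cells <- expand.grid(q = q_range, d = d_grid, p = p_range,
                       KEEP.OUT.ATTRS = FALSE)[, c("p", "d", "q")]
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    fits[[i]] <- fit_arima(w, cells$p[i], cells$d[i], cells$q[i],
                           pre_diff = pre_diff)
  }
  records <- do.call(rbind, lapply(fits, function(f) {
    data.frame(p = f$p, d = f$d, q = f$q, total_d = f$total_d, aic = f$aic,
               bic = f$bic, ll = f$ll, converged = f$converged,
               fit_seconds = f$fit_seconds)
  }))
  best_idx <- select_optimal(records, criterion, index = TRUE)
  obj <- list(records = records,
              best = if (is.na(best_idx)) NULL else fits[[best_idx]],
              criterion = criterion, series = w, pre_diff = as.integer(pre_diff),
              call = match.call())
  class(obj) <- "arima_grid"
  obj
}

#' Select the optimal grid cell by a criterion
#'
#' Minimizes AIC or BIC, maximizes LL. Ties are broken by smaller `p + q`,
#' then smaller `p`.
#'
#' @param records data.frame of grid records (columns `p, d, q, total_d, aic,
#'   bic, ll, converged`).
#' @param criterion `"aic"`, `"bic"` or `"ll"`.
#' @param index Return the row index instead of the spec row.
#' @return One-row data.frame (the optimal spec), or `NA` row index / `NULL`
#'   when no cell converged.
#' @export
select_optimal <- function(records, criterion = c("aic", "bic", "ll"),
                           index = FALSE) {
  criterion <- match.arg(criterion)
  ok <- which(records$converged & is.finite(records[[criterion]]))
  if (!length(ok)) {
    if (index) return(NA_integer_)
    return(NULL)
  }
  score <- records[[criterion]][ok]
  if (criterion == "ll") score <- -score
  best_score <- min(score)
  cand <- ok[score <= best_score + 1e-10]
  if (length(cand) > 1L) {
    o <- order(records$p[cand] + records$q[cand], records$p[cand])
    cand <- cand[o]
  }
  if (index) return(cand[1L])
  records[cand[1L], , drop = FALSE]
}

#' Component-wise population median of per-patient optimal orders
#'
#' Medians of `(p, total_d, q)` over per-patient optima within each signal x
#' resolution cell; half-point medians are rounded down to the simpler
#' (lower-order) model. The median of the criterion values is reported
#' alongside.
#'
#' @param optima data.frame with columns `signal, resolution, p, total_d, q`
#'   and a criterion-value column named by `criterion`.
#' @param criterion Which criterion value column to summarize.
#' @return data.frame with `signal, resolution, criterion, median_p,
#'   median_d, median_q, median_value, n_patients`; empty cells are omitted.
#' @export
population_median_models <- function(optima, criterion = "aic") {
  med_int <- function(v) as.integer(floor(stats::median(v)))
  cells <- unique(optima[c("signal", "resolution")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- optima[optima$signal == cells$signal[i] &
                    optima$resolution == cells$resolution[i], ]
    sub <- sub[!is.na(sub$p), , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(signal = cells$signal[i], resolution = cells$resolution[i],
               criterion = toupper(criterion),
               median_p = med_int(sub$p), median_d = med_int(sub$total_d),
               median_q = med_int(sub$q),
               median_value = stats::median(sub[[criterion]]),
               n_patients = nrow(sub))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(signal = character(0), resolution = numeric(0),
                      criterion = character(0), median_p = integer(0),
                      median_d = integer(0), median_q = integer(0),
                      median_value = numeric(0), n_patients = integer(0))
  }
  out
}

#' Residual whitening diagnostics
#'
#' Autocorrelation and partial autocorrelation of the raw series and of the
#' fit residuals at lags `1..n_lags`, with the 95% band `+/- 1.96 / sqrt(n)`,
#' and the proportion of lags outside the band before and after modeling.
#'
#' @param grid_fit An `arima_grid` object (or an `arima_fit` with its series
#'   passed via `series`).
#' @param n_lags Number of lags; truncated with a warning if it reaches the
#'   series length.
#' @param series Raw series override (defaults to the grid's series).
#' @return List with `residuals`, `acf_raw`, `pacf_raw`, `acf_res`,
#'   `pacf_res`, `band`, `prop_significant_pre`, `prop_significant_post`.
#' @export
residual_diagnostics <- function(grid_fit, n_lags = 40L, series = NULL) {
  if (inherits(grid_fit, "arima_grid")) {
    best <- grid_fit$best
    if (is.null(series)) series <- grid_fit$series
  } else {
    best <- grid_fit
  }
  if (is.null(best) || !best$converged) {
    stop("diagnostics require a converged fit", call. = FALSE)
  }
  res <- as.numeric(stats::residuals(best$fit))
  n_eff <- best$n_eff
  if (n_lags >= n_eff) {
    warning("n_lags >= effective length; truncating")
    n_lags <- n_eff - 1L
  }
  band <- 1.96 / sqrt(n_eff)
  acf_of <- function(v) {
    drop(stats::acf(v, lag.max = n_lags, plot = FALSE,
                    na.action = stats::na.pass)$acf)[-1]
  }
  pacf_of <- function(v) {
    drop(stats::pacf(v, lag.max = n_lags, plot = FALSE,
                     na.action = stats::na.pass)$acf)
  }
  acf_raw <- acf_of(series); acf_res <- acf_of(res)
  list(residuals = res,
       acf_raw = acf_raw, pacf_raw = pacf_of(series),
       acf_res = acf_res, pacf_res = pacf_of(res),
       band = band,
       prop_significant_pre = mean(abs(acf_raw) > band),
       prop_significant_post = mean(abs(acf_res) > band))
}
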