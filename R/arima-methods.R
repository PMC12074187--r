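# S3 methods for arima_grid objects.

#' @export
print.arima_grid <- function(x, ...) {
  cat("ARIMA grid search (", nrow(x$records), " cells, criterion = ",
      toupper(x$criterion), ")\n", sep = "")
  if (is.null(x$best)) {
    cat("  no converged fit\n")
    return(invisible(x))
  }
  b <- x$best
  cat(sprintf("  optimal order: (p, d, q) = (%d, %d, %d)  [total d = %d incl. pre-differencing]\n",
              b$p, b$d, b$q, b$total_d))
  cat(sprintf("  AIC %.2f  BIC %.2f  logLik %.2f  sigma^2 %.4g  (n_eff = %d)\n",
              b$aic, b$bic, b$ll, b$sigma2, b$n_eff))
  invisible(x)
}

#' @export
summary.arima_grid <- function(object, ...) {
  rec <- object$records
  tops <- lapply(c("aic", "bic", "ll"), function(cr) {
    row <- select_optimal(rec, cr)
    if (is.null(row)) return(NULL)
    cbind(criterion = toupper(cr), row[c("p", "d", "q", "total_d", cr)],
          value = row[[cr]])[, c("criterion", "p", "d", "q", "total_d", "value")]
  })
  out <- list(optima = do.call(rbind, tops),
              n_cells = nrow(rec),
              n_converged = sum(rec$converged),
              criterion = object$criterion)
  class(out) <- "summary.arima_grid"
  out
}

#' @export
print.summary.arima_grid <- function(x, ...) {
  cat("Grid:", x$n_cells, "cells,", x$n_converged, "converged\n")
  cat("Optima by criterion (value = AIC/BIC minimized, LL maximized):\n")
  print(x$optima, row.names = FALSE)
  invisible(x)
}

#' @export
coef.arima_grid <- function(object, ...) {
  if (is.null(object$best)) return(numeric(0))
  object$best$coef
}

#' @export
residuals.arima_grid <- function(object, ...) {
  if (is.null(object$best)) stop("no converged fit", call. = FALSE)
  as.numeric(stats::residuals(object$best$fit))
}

#' @export
logLik.arima_grid <- function(object, ...) {
  if (is.null(object$best)) return(NA_real_)
  structure(object$best$ll, df = object$best$p + object$best$q + 1L,
            class = "logLik")
}

#' Forecasts from the selected grid optimum
#'
#' With `n.ahead` given, returns the usual multi-step forecast from the end
#' of the series. Otherwise runs the rolling one-step-ahead evaluation
#' ([rolling_one_step()]) on the grid's series with the optimum orders.
#' @param object An `arima_grid`.
#' @param n.ahead Steps ahead for a terminal forecast, or `NULL` (default)
#'   for the rolling one-step evaluation.
#' @param ... Passed to [rolling_one_step()].
#' @export
predict.arima_grid <- function(object, n.ahead = NULL, ...) {
  if (is.null(object$best)) stop("no converged fit", call. = FALSE)
  if (!is.null(n.ahead)) {
    return(stats::predict(object$best$fit, n.ahead = n.ahead))
  }
  b <- object$best
  rolling_one_step(object$series, order = c(b$p, b$d, b$q), ...)
}

#' Residual diagnostic panels for a grid fit
#'
#' Six base-graphics panels: the raw series with its ACF and PACF, and the
#' optimum-model residuals with theirs, each with the 95% band.
#' @param x An `arima_grid`.
#' @param n_lags Lags shown.
#' @param ... Ignored.
#' @export
plot.arima_grid <- function(x, n_lags = 40L, ...) {
  d <- residual_diagnostics(x, n_lags = n_lags)
  old <- graphics::par(mfrow = c(3, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  bar <- function(v, main) {
    graphics::plot(seq_along(v), v, type = "h", xlab = "lag", ylab = "",
                   main = main, ylim = range(c(v, d$band, -d$band)))
    graphics::abline(h = c(-d$band, d$band), lty = 2, col = "steelblue")
    graphics::abline(h = 0)
  }
  graphics::plot(x$series, type = "l", xlab = "t", ylab = "",
                 main = "series (pre-differenced)")
  graphics::plot(d$residuals, type = "l", xlab = "t", ylab = "",
                 main = "residuals")
  bar(d$acf_raw, "ACF: series")
  bar(d$acf_res, "ACF: residuals")
  bar(d$pacf_raw, "PACF: series")
  bar(d$pacf_res, "PACF: residuals")
  invisible(x)
}

#' Simulate from the selected grid optimum
#'
#' Draws new series from the fitted coefficients via
#' [simulate_arima_series()], on the total-differencing scale of the original
#' (undifferenced) input.
#' @param object An `arima_grid`.
#' @param nsim Series length (defaults to the fitted length).
#' @param seed Integer seed.
#' @param ... Ignored.
#' @export
simulate.arima_grid <- function(object, nsim = NULL, seed = 1L, ...) {
  b <- object$best
  if (is.null(b)) stop("no converged fit", call. = FALSE)
  if (is.null(nsim)) nsim <- length(object$series) + object$pre_diff
  phi <- b$coef[grep("^ar", names(b$coef))]
  theta <- b$coef[grep("^ma", names(b$coef))]
  simulate_arima_series(b$p, b$total_d, b$q, unname(phi), unname(theta),
                        sqrt(b$sigma2), n = nsim, seed = seed)
}
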