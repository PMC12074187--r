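test_that("fit_arima recovers known coefficients and reports criteria identities", {
  x <- simulate_arima_series(1, 0, 0, ar_coeffs = 0.8, n = 5000, seed = 1)
  f <- fit_arima(x, 1, 0, 0)
  expect_true(f$converged)
  expect_equal(unname(f$coef["ar1"]), 0.8, tolerance = 0.05)
  # aic - bic = k * (2 - log(n_eff)) for every converged fit
  k <- f$p + f$q + 1L + 1L  # constant (d = 0) + variance
  expect_equal(f$aic - f$bic, k * (2 - log(f$n_eff)), tolerance = 1e-8)

  wn <- simulate_arima_series(0, 0, 0, n = 2000, seed = 2)
  f2 <- fit_arima(wn, 1, 0, 0)
  expect_lt(abs(unname(f2$coef["ar1"])), 0.1)
})

test_that("degenerate and failed fits yield non-converged records, never errors", {
  f <- fit_arima(rep(1, 100), 2, 0, 2)
  expect_false(f$converged)
  expect_equal(f$aic, Inf)
  expect_equal(f$ll, -Inf)
  # series shorter than k + 2
  f2 <- fit_arima(rnorm(5), 3, 0, 3)
  expect_false(f2$converged)
})

test_that("grid search enumerates every cell and its optimum is reproducible", {
  x <- simulate_arima_series(1, 1, 1, 0.5, 0.3, 1, n = 300, seed = 5)
  g <- arima_grid(x, p_range = 1:3, d_grid = 0L, q_range = 0:2, pre_diff = 1L)
  expect_equal(nrow(g$records), 9L)
  g_def <- arima_grid(simulate_arima_series(1, 1, 1, 0.5, 0.3, 1, 300, seed = 5),
                      p_range = 1:3, d_grid = 0L, q_range = 0:2)
  expect_equal(g$records$aic, g_def$records$aic)
  # refitting the winning cell alone reproduces its criteria
  b <- g$best
  refit <- fit_arima(g$series, b$p, b$d, b$q)
  expect_equal(refit$aic, b$aic, tolerance = 1e-6)
  expect_error(arima_grid(x, p_range = integer(0)), "empty grid")
  expect_error(arima_grid(rnorm(20), p_range = 1:2), "too short")
  # default grid dimensions: 10 x 2 x 11
  cells <- expand.grid(p = 1:10, d = 0:1, q = 0:10)
  expect_equal(nrow(cells), 220L)
})

test_that("select_optimal minimizes, maximizes LL, and breaks ties to simpler models", {
  rec <- data.frame(p = c(3, 2, 1), d = 0, q = c(2, 2, 0),
                    total_d = 1, aic = c(10, 8, 9), bic = c(11, 9, 10),
                    ll = c(-1, -2, -3), converged = TRUE)
  expect_equal(select_optimal(rec, "aic")$p, 2)
  # tie at AIC 8 between (3,0,2) and (2,0,2) -> (2,0,2)
  rec$aic <- c(8, 8, 9)
  best <- select_optimal(rec, "aic")
  expect_equal(c(best$p, best$q), c(2, 2))
  # LL is argmax
  expect_equal(select_optimal(rec, "ll")$p, 3)
  # non-converged rows are ignored; all non-converged -> NULL
  rec$converged <- FALSE
  expect_null(select_optimal(rec, "aic"))
})

test_that("population medians are component-wise with half rounded down", {
  optima <- data.frame(signal = "ICP", resolution = 1,
                       p = c(4, 4, 3), total_d = 1, q = c(5, 4, 6),
                       aic = c(100, 90, 95))
  m <- population_median_models(optima)
  expect_equal(c(m$median_p, m$median_d, m$median_q), c(4L, 1L, 5L))
  expect_equal(m$median_value, 95)
  # two-patient cell: half-point medians round down to the simpler order
  optima2 <- data.frame(signal = "MAP", resolution = 1,
                        p = c(2, 4), total_d = 1, q = c(1, 3),
                        aic = c(10, 20))
  m2 <- population_median_models(optima2)
  expect_equal(c(m2$median_p, m2$median_q), c(3L, 2L))
  optima3 <- data.frame(signal = "MAP", resolution = 1,
                        p = c(2, 3), total_d = c(1, 2), q = c(1, 2),
                        aic = c(10, 20))
  m3 <- population_median_models(optima3)
  expect_equal(c(m3$median_p, m3$median_d, m3$median_q), c(2L, 1L, 1L))
})

test_that("residual diagnostics whiten a correctly specified fit", {
  x <- simulate_arima_series(1, 0, 0, 0.8, n = 400, seed = 9)
  g <- arima_grid(x, p_range = 1:2, d_grid = 0L, q_range = 0:1, pre_diff = 0L)
  d <- residual_diagnostics(g)
  expect_equal(d$band, 1.96 / sqrt(400), tolerance = 1e-6)
  # raw AR(1) phi=0.8: analytic ACF phi^k exceeds the band at early lags
  expect_gt(d$prop_significant_pre, 0.05)
  expect_true(all(abs(d$acf_raw[1:3] - 0.8^(1:3)) < 0.15))
  expect_lt(d$prop_significant_post, 0.15)
  expect_warning(residual_diagnostics(g, n_lags = 400), "truncating")
})

test_that("criterion complexity ordering holds as a tendency over seeds", {
  # BIC-selected p+q <= AIC-selected p+q <= LL-selected p+q in most replicates
  ok <- vapply(1:20, function(s) {
    x <- simulate_arima_series(2, 1, 1, c(0.5, -0.3), 0.4, 1, n = 500,
                               seed = 100 + s)
    g <- arima_grid(x, p_range = 1:4, d_grid = 0L, q_range = 0:3)
    oa <- select_optimal(g$records, "aic")
    ob <- select_optimal(g$records, "bic")
    ol <- select_optimal(g$records, "ll")
    (ob$p + ob$q) <= (oa$p + oa$q) && (oa$p + oa$q) <= (ol$p + ol$q)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("arima_grid methods print, summarize, and simulate coherently", {
  x <- simulate_arima_series(1, 1, 0, 0.6, n = 300, seed = 3)
  g <- arima_grid(x, p_range = 1:2, d_grid = 0:1, q_range = 0:1)
  expect_output(print(g), "optimal order")
  s <- summary(g)
  expect_equal(nrow(s$optima), 3L)
  expect_named(coef(g))
  expect_equal(length(residuals(g)), length(g$series))
  y <- simulate(g, nsim = 200, seed = 4)
  expect_equal(length(y), 200L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(g))
})
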