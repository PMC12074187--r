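test_that("identical config and seed give bit-identical waveforms", {
  cfg <- sim_config(seed = 11, duration = 5)
  a <- simulate_waveforms(cfg)
  b <- simulate_waveforms(cfg)
  expect_identical(a, b)
})

test_that("noiseless passive coupling copies the slow wave into ICP", {
  cfg <- sim_config(seed = 2, duration = 20, autoregulation_gain = 1,
                    noise_sd = c(ABP = 0, ICP = 0, rSO2_L = 0, rSO2_R = 0,
                                 PbtO2 = 0))
  wf <- simulate_waveforms(cfg)
  # 10-s means strip the cardiac tone (not an integer number of cycles per
  # frame, but attenuated ~1000x); slow components must correlate at +1
  abp10 <- ten_second_means(wf$channels$ABP, cfg$sampling_rate)
  icp10 <- ten_second_means(wf$channels$ICP, cfg$sampling_rate)
  expect_gt(cor(abp10, icp10), 0.99)
  # and the ICP slow component is a 0.5-scaled copy of the ABP slow component
  slope <- coef(lm(icp10 ~ abp10))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.05)
})

test_that("zero slow-wave amplitude leaves only baseline plus cardiac tone", {
  cfg <- sim_config(seed = 5, duration = 2, slow_wave_amp = 0,
                    noise_sd = c(ABP = 0, ICP = 0, rSO2_L = 0, rSO2_R = 0,
                                 PbtO2 = 0))
  wf <- simulate_waveforms(cfg)
  t <- (seq_along(wf$channels$ABP) - 1) / cfg$sampling_rate
  resid <- wf$channels$ABP - cfg$map_baseline -
    cfg$cardiac_amp_abp * sin(2 * pi * cfg$cardiac_freq * t)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("spectral peaks of noiseless ABP sit at the cardiac tone and slow band", {
  cfg <- sim_config(seed = 9, duration = 30,
                    noise_sd = c(ABP = 0, ICP = 0, rSO2_L = 0, rSO2_R = 0,
                                 PbtO2 = 0))
  wf <- simulate_waveforms(cfg)
  x <- wf$channels$ABP - mean(wf$channels$ABP)
  n <- length(x)
  spec <- Mod(fft(x))[1:(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * cfg$sampling_rate / n
  big <- freqs[spec > 0.01 * max(spec)]
  in_slow <- big >= cfg$slow_wave_band[1] - 1e-3 &
    big <= cfg$slow_wave_band[2] + 1e-3
  at_cardiac <- abs(big - cfg$cardiac_freq) < 0.01
  expect_true(all(in_slow | at_cardiac))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(duration = -1), "positive")
  expect_error(sim_config(sampling_rate = 2, cardiac_freq = 1.2), "4 \\* cardiac_freq")
  expect_error(sim_config(slow_wave_band = c(0.5, 2)), "slow_wave_band")
  expect_error(sim_config(autoregulation_gain = 1.5), "\\[-1, 1\\]")
  expect_error(sim_config(slow_wave_amp = -2), "nonnegative")
})

test_that("pure ARIMA generator matches its defining recursions", {
  # iid noise: sample variance approaches the innovation variance
  x <- simulate_arima_series(0, 0, 0, innovation_sd = 2, n = 20000, seed = 4)
  expect_equal(var(x), 4, tolerance = 0.1)
  # d = 1 pure integration: first difference is iid (lag-1 ACF near 0)
  w <- simulate_arima_series(0, 1, 0, n = 5000, seed = 4)
  r1 <- acf(diff(w), lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.05)
  # AR(1) phi = 0.8: lag-1 sample autocorrelation within +/- 0.05
  y <- simulate_arima_series(1, 0, 0, ar_coeffs = 0.8, n = 5000, seed = 1)
  expect_equal(acf(y, lag.max = 1, plot = FALSE)$acf[2], 0.8,
               tolerance = 0.05)
  # determinism
  expect_identical(y, simulate_arima_series(1, 0, 0, ar_coeffs = 0.8,
                                            n = 5000, seed = 1))
})

test_that("ARIMA generator rejects invalid polynomials and lengths", {
  expect_error(simulate_arima_series(1, 0, 0, ar_coeffs = 1.1, n = 100),
               "non-stationary")
  expect_error(simulate_arima_series(0, 0, 1, ma_coeffs = -1.5, n = 100),
               "non-invertible")
  expect_error(simulate_arima_series(2, 1, 2, c(0.5, -0.3), c(0.4, 0.2),
                                     n = 5), "exceed")
})

test_that("cohort covariates follow their stated marginals", {
  cfg <- sim_config(seed = 17, n_patients = 100)
  cohort <- simulate_cohort(cfg, waveforms = FALSE)
  male_frac <- mean(cohort$meta$sex == "M")
  # binomial 95% bounds around 0.78 at n = 100
  expect_gt(male_frac, 0.78 - 1.96 * sqrt(0.78 * 0.22 / 100))
  expect_lt(male_frac, 0.78 + 1.96 * sqrt(0.78 * 0.22 / 100))
  expect_setequal(unique(cohort$meta$marshall_group), c(">=5", "<5"))
  expect_true(all(cohort$meta$pupils %in%
                    c("bilateral reactive", "unilateral unreactive",
                      "bilateral unreactive")))
})

test_that("subgroup effects shift only the targeted stratum", {
  cfg <- sim_config(seed = 1, n_patients = 6, duration = 3,
                    subgroup_effects = list(marshall_ge5 =
                                              list(map_baseline = 30)))
  cohort <- simulate_cohort(cfg)
  means <- vapply(cohort$waveforms,
                  function(w) mean(w$channels$ABP), numeric(1))
  hi <- cohort$meta$marshall >= 5
  skip_if(!any(hi) || all(hi))  # improbable draw with both strata empty
  expect_true(min(means[hi]) > max(means[!hi]))
  expect_error(
    simulate_cohort(sim_config(seed = 1, n_patients = 2,
                               subgroup_effects = list(bogus = list())),
                    waveforms = FALSE),
    "unknown covariate level")
})

test_that("inject_gaps writes exactly the requested runs", {
  x <- 1:50
  y <- inject_gaps(x, list(c(10, 3)))
  expect_identical(which(is.na(y)), 10:12)
  expect_identical(y[-(10:12)], as.numeric(x[-(10:12)]))
  expect_identical(inject_gaps(x, list()), 1:50)
  y2 <- inject_gaps(x, list(c(5, 2), c(20, 7)))
  expect_identical(sum(is.na(y2)), 9L)
  expect_error(inject_gaps(x, list(c(5, 3), c(6, 2))), "overlap")
  expect_error(inject_gaps(x, list(c(48, 5))), "bounds")
})

test_that("waveform CSV round-trips through write and read", {
  cfg <- sim_config(seed = 8, duration = 1, gap_spec = list(c(1, 1)))
  wf <- simulate_waveforms(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  back <- read_waveform_csv(path)
  expect_equal(back$patient_id, wf$patient_id)
  expect_equal(back$sampling_rate, wf$sampling_rate)
  expect_equal(back$channels$ABP, wf$channels$ABP, tolerance = 1e-6)
  expect_true(all(is.na(back$channels$ICP[1:100])))
})
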