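test_that("ten_second_means averages half-open frames and propagates NA", {
  expect_equal(ten_second_means(rep(80, 600), 1), rep(80, 60))
  # ramp 0..599 at 1 Hz: first frame holds samples 0..9, mean 4.5
  m <- ten_second_means(0:599, 1)
  expect_equal(m[1], 4.5)
  expect_equal(m, seq(4.5, by = 10, length.out = 60))
  # full cardiac cycles per frame average to zero
  t <- (0:5999) / 10
  m2 <- ten_second_means(sin(2 * pi * 1.2 * t), 10)
  expect_lt(max(abs(m2)), 1e-12)
  # NA anywhere in a frame -> NA for that frame only
  x <- rep(1, 30); x[12] <- NA
  expect_equal(ten_second_means(x, 1), c(1, NA, 1))
  expect_identical(ten_second_means(numeric(0), 50), numeric(0))
})

test_that("ten_second_means commutes with affine rescaling", {
  set.seed(1)
  x <- rnorm(3000)
  expect_equal(ten_second_means(3 * x + 7, 10),
               3 * ten_second_means(x, 10) + 7)
})

test_that("compute_amp recovers single-tone amplitude and ignores out-of-band energy", {
  icp <- pure_tone(amp = 2, freq = 1.2, fs = 50, minutes = 2)
  amp <- compute_amp(icp, 50)
  expect_true(all(abs(amp - 2) < 0.04))  # 2.0 within 2%
  # constant input: zero spectrum after demeaning
  expect_equal(compute_amp(rep(10, 3000), 50), rep(0, 6))
  # slow tone outside the cardiac band does not contribute
  t <- (0:(50 * 120 - 1)) / 50
  two <- 10 + 2 * sin(2 * pi * 1.2 * t) + 1 * sin(2 * pi * 0.02 * t)
  expect_true(all(abs(compute_amp(two, 50) - 2) < 0.08))
  # invariant to adding a constant
  expect_equal(compute_amp(icp + 37, 50), amp)
  # NA frames propagate
  icp[30] <- NA
  expect_true(is.na(compute_amp(icp, 50)[1]))
  expect_error(compute_amp(icp, 50, cardiac_band = c(30, 40)), "Nyquist")
})

test_that("compute_cpp is NA-propagating elementwise subtraction", {
  expect_equal(compute_cpp(86.9, 11.9), 75)
  expect_equal(compute_cpp(c(80, 80), c(80, NA)), c(0, NA))
  expect_error(compute_cpp(1:3, 1:2), "aligned")
})

test_that("moving_correlation obeys its window and degeneracy rules", {
  x <- rnorm(180) + seq(0, 3, length.out = 180)
  up <- moving_correlation(x, x)
  expect_true(all(is.na(up[1:4])))         # window reaches before start
  expect_true(all(abs(up[5:30] - 1) < 1e-12))
  expect_true(all(abs(moving_correlation(x, -x)[5:30] + 1) < 1e-12))
  xc <- x; xc[31:60] <- 5                  # constant window -> NA
  mc <- moving_correlation(xc, rnorm(180))
  expect_true(anyNA(mc[6:10]))
  expect_error(moving_correlation(x, x, update_samples = 0), "positive")
  expect_error(moving_correlation(x, x[-1]), "aligned")
})

test_that("independent series give near-zero mean moving correlation", {
  set.seed(42)
  n_win <- 200
  x <- rnorm(30 + 6 * n_win)
  y <- rnorm(30 + 6 * n_win)
  r <- moving_correlation(x, y)
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.05)
  expect_true(all(abs(r) <= 1, na.rm = TRUE))
})

test_that("derive_indices reflects the autoregulation coupling sign", {
  mt_pos <- derive_indices(simulate_waveforms(low_noise_config(g = 1)))
  expect_gt(median(mt_pos$PRx, na.rm = TRUE), 0.8)
  mt_neg <- derive_indices(simulate_waveforms(low_noise_config(g = -1)))
  expect_lt(median(mt_neg$PRx, na.rm = TRUE), -0.5)
  # all indices bounded
  for (idx in c("PRx", "PAx", "RAC", "RAP", "COx_L", "COx-a_R")) {
    expect_true(all(abs(mt_pos[[idx]]) <= 1, na.rm = TRUE), info = idx)
  }
  # CPP + ICP = MAP wherever all three defined
  expect_lt(max(abs(mt_pos$CPP + mt_pos$ICP - mt_pos$MAP), na.rm = TRUE),
            1e-9)
})

test_that("missing oximetry channels yield NA index columns only", {
  wf <- simulate_waveforms(low_noise_config())
  wf$channels$rSO2_L <- NULL
  wf$channels$rSO2_R <- NULL
  mt <- derive_indices(wf)
  expect_true(all(is.na(mt$COx_L)))
  expect_true(all(is.na(mt[["COx-a_R"]])))
  expect_gt(median(mt$PRx, na.rm = TRUE), 0.8)  # PRx unaffected
})
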