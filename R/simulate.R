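# Synthetic cohort generator: seeded waveforms, pure ARIMA test series, and
# patient metadata with known ground truth. The waveform model is a
# sum-of-sinusoids-plus-noise abstraction, not a hemodynamic ODE: arterial
# pressure carries a cardiac tone plus slow vasogenic oscillations
# (0.005-0.05 Hz); intracranial pressure receives the slow component through a
# tunable autoregulation coupling g in [-1, 1] (+1 = fully passive pressure
# transmission, -1 = active counter-regulation), which fixes the expected sign
# of the downstream pressure-reactivity index.

#' Simulation configuration for the synthetic cohort
#'
#' Collects every tunable of the waveform simulator in one validated object.
#' Defaults are chosen to emulate an adult TBI neuromonitoring recording at
#' desk scale: mean arterial pressure around 87 mmHg and intracranial pressure
#' around 12 mmHg (typical cohort means), a 1.2 Hz (72 bpm) cardiac tone
#' sampled at 50 Hz, and slow vasogenic oscillations confined to
#' 0.005--0.05 Hz.
#'
#' @param seed Integer seed; identical configurations (including seed)
#'   reproduce bit-identical output.
#' @param n_patients Number of patients for [simulate_cohort()].
#' @param duration Recording length in minutes.
#' @param sampling_rate Waveform sampling rate in Hz. Must be at least
#'   `4 * cardiac_freq` so the cardiac harmonic stays well inside Nyquist.
#' @param map_baseline,icp_baseline Baseline mean arterial / intracranial
#'   pressure, mmHg.
#' @param cardiac_freq Cardiac frequency, Hz.
#' @param cardiac_amp_abp,cardiac_amp_icp Amplitude of the cardiac sinusoid in
#'   the ABP / ICP channel, mmHg.
#' @param slow_wave_band Two-element Hz interval holding the slow vasogenic
#'   oscillations; must lie strictly between 0 and `cardiac_freq`.
#' @param slow_wave_amp Total amplitude scale of the slow-wave component, mmHg.
#' @param autoregulation_gain Coupling `g` in `[-1, 1]` between the ABP slow
#'   component and ICP: `+1` is fully passive pressure transmission (expected
#'   PRx near +1), `-1` is counter-regulation (negative PRx), `0` decouples
#'   the channels.
#' @param noise_sd Named numeric vector of per-channel white-noise standard
#'   deviations (signal units); names among `ABP, ICP, rSO2_L, rSO2_R, PbtO2`.
#' @param gap_spec Optional list of `c(start_minute, run_length)` pairs; the
#'   stated minutes are written as missing in every channel.
#' @param rso2_baseline,pbto2_baseline Baselines for the oximetry channels
#'   (% and mmHg).
#' @param subgroup_effects Optional named list mapping a covariate level (for
#'   example `"marshall_ge5"`) to a named list of parameter offsets applied to
#'   affected patients (multiplicative for `noise_sd_scale`, additive
#'   otherwise).
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, duration = 30)
#' wf <- simulate_waveforms(cfg)
#' str(wf$channels$ABP[1:5])
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 1L,
                       duration = 120,
                       sampling_rate = 50,
                       map_baseline = 87,
                       icp_baseline = 12,
                       cardiac_freq = 1.2,
                       cardiac_amp_abp = 20,
                       cardiac_amp_icp = 2,
                       slow_wave_band = c(0.005, 0.05),
                       slow_wave_amp = 5,
                       autoregulation_gain = 1,
                       noise_sd = c(ABP = 1, ICP = 0.5, rSO2_L = 0.5,
                                    rSO2_R = 0.5, PbtO2 = 0.5),
                       gap_spec = list(),
                       rso2_baseline = 70,
                       pbto2_baseline = 25,
                       subgroup_effects = list()) {
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar_number(cardiac_freq, "cardiac_freq", positive = TRUE)
  if (sampling_rate < 4 * cardiac_freq) {
    stop("sampling_rate must be >= 4 * cardiac_freq", call. = FALSE)
  }
  if (length(slow_wave_band) != 2L || any(slow_wave_band <= 0) ||
      slow_wave_band[1] >= slow_wave_band[2] ||
      slow_wave_band[2] >= cardiac_freq) {
    stop("slow_wave_band must be an increasing interval inside (0, cardiac_freq)",
         call. = FALSE)
  }
  if (abs(autoregulation_gain) > 1) {
    stop("autoregulation_gain must lie in [-1, 1]", call. = FALSE)
  }
  if (any(c(cardiac_amp_abp, cardiac_amp_icp, slow_wave_amp) < 0) ||
      any(noise_sd < 0)) {
    stop("amplitudes and noise_sd must be nonnegative", call. = FALSE)
  }
  if (length(gap_spec)) validate_gap_spec(gap_spec, duration)
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    duration = duration, sampling_rate = sampling_rate,
    map_baseline = map_baseline, icp_baseline = icp_baseline,
    cardiac_freq = cardiac_freq, cardiac_amp_abp = cardiac_amp_abp,
    cardiac_amp_icp = cardiac_amp_icp, slow_wave_band = slow_wave_band,
    slow_wave_amp = slow_wave_amp, autoregulation_gain = autoregulation_gain,
    noise_sd = noise_sd, gap_spec = gap_spec,
    rso2_baseline = rso2_baseline, pbto2_baseline = pbto2_baseline,
    subgroup_effects = subgroup_effects
  ), class = "sim_config")
}

validate_gap_spec <- function(gap_spec, duration) {
  spans <- lapply(gap_spec, function(g) {
    if (length(g) != 2L || any(g < 1)) {
      stop("each gap must be c(start_minute, run_length) with positive entries",
           call. = FALSE)
    }
    seq(g[1], g[1] + g[2] - 1L)
  })
  all_min <- unlist(spans)
  if (anyDuplicated(all_min)) stop("gap runs must not overlap", call. = FALSE)
  if (max(all_min) > duration) stop("gap run exceeds series bounds", call. = FALSE)
  invisible(spans)
}

# Random-phase sum of sinusoids confined to the slow-wave band. Uses a fixed
# number of components; per-component amplitude scaled so the summed signal's
# amplitude is of order `amp`.
slow_wave_component <- function(t, band, amp, n_components = 6L) {
  freqs <- stats::runif(n_components, band[1], band[2])
  phases <- stats::runif(n_components, 0, 2 * pi)
  a <- amp / sqrt(n_components)
  s <- numeric(length(t))
  for (k in seq_len(n_components)) {
    s <- s + a * sin(2 * pi * freqs[k] * t + phases[k])
  }
  s
}

#' Simulate one patient's multichannel waveform record
#'
#' Generates ABP, ICP, bilateral rSO2 and PbtO2 at the configured sampling
#' rate. The ABP slow-wave component is transmitted into ICP scaled by
#' `autoregulation_gain * kappa` (fixed attenuation `kappa = 0.5`); cardiac
#' sinusoids in the two pressure channels are independently phased. The rSO2
#' channels follow the slow component of perfusion pressure (ABP minus ICP)
#' with a gain sharing the sign of the autoregulation coupling; PbtO2 is a
#' smoothed slow drift plus noise. Declared gap minutes are written as `NA` in
#' every channel.
#'
#' @param config A [sim_config()] object.
#' @param patient_id Identifier stored on the record.
#' @return A `waveform_record`: list with `patient_id`, `channels` (named list
#'   of equal-length numeric vectors), `sampling_rate`, and `t0`.
#' @export
simulate_waveforms <- function(config, patient_id = "P001") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 0L, simulate_waveforms_impl(config, patient_id))
}

simulate_waveforms_impl <- function(config, patient_id) {
  fs <- config$sampling_rate
  n <- round(config$duration * 60 * fs)
  t <- (seq_len(n) - 1) / fs
  kappa <- 0.5

  s <- slow_wave_component(t, config$slow_wave_band, config$slow_wave_amp)
  phi_icp <- stats::runif(1, 0, 2 * pi)
  nsd <- function(ch) {
    v <- config$noise_sd[ch]
    if (is.na(v)) 0 else unname(v)
  }
  noise <- function(ch) {
    sd <- nsd(ch)
    if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  }

  abp <- config$map_baseline + s +
    config$cardiac_amp_abp * sin(2 * pi * config$cardiac_freq * t) +
    noise("ABP")
  icp_slow <- config$autoregulation_gain * kappa * s
  icp <- config$icp_baseline + icp_slow +
    config$cardiac_amp_icp * sin(2 * pi * config$cardiac_freq * t + phi_icp) +
    noise("ICP")

  # rSO2 tracks the slow component of CPP = ABP - ICP; gain carries sign(g)
  g <- config$autoregulation_gain
  h <- 0.2 * if (g == 0) 1 else sign(g)
  cpp_slow <- s - icp_slow
  rso2_l <- config$rso2_baseline + h * cpp_slow + noise("rSO2_L")
  rso2_r <- config$rso2_baseline + h * cpp_slow + noise("rSO2_R")

  # PbtO2: slow drift (smoothed random walk at minute scale) + noise
  n_min <- max(2L, ceiling(config$duration))
  drift_knots <- cumsum(stats::rnorm(n_min, 0, 0.3))
  drift <- stats::approx(seq(0, config$duration * 60, length.out = n_min),
                         drift_knots, xout = t, rule = 2)$y
  pbto2 <- config$pbto2_baseline + drift + noise("PbtO2")

  channels <- list(ABP = abp, ICP = icp, rSO2_L = rso2_l, rSO2_R = rso2_r,
                   PbtO2 = pbto2)
  if (length(config$gap_spec)) {
    for (gpair in config$gap_spec) {
      idx_start <- round((gpair[1] - 1) * 60 * fs) + 1L
      idx_end <- min(n, round((gpair[1] - 1 + gpair[2]) * 60 * fs))
      channels <- lapply(channels, function(ch) {
        ch[idx_start:idx_end] <- NA_real_
        ch
      })
    }
  }
  structure(list(patient_id = patient_id, channels = channels,
                 sampling_rate = fs, t0 = 0),
            class = "waveform_record")
}

#' Simulate a pure ARIMA(p, d, q) series with known coefficients
#'
#' Ground-truth generator for order-recovery experiments: draws seeded
#' Gaussian innovations, runs the ARMA recursion on the differenced scale with
#' a burn-in of at least `10 * (p + q)` samples discarded, then integrates `d`
#' times by cumulative summation.
#'
#' @param p,d,q Nonnegative integer orders.
#' @param ar_coeffs,ma_coeffs Coefficient vectors of lengths `p` and `q`.
#' @param innovation_sd Standard deviation of the Gaussian innovations.
#' @param n Output length; must exceed `p + q + d`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_arima_series(1, 0, 0, ar_coeffs = 0.8, n = 500, seed = 1)
#' acf(x, lag.max = 1, plot = FALSE)$acf[2]  # close to 0.8
#' @export
simulate_arima_series <- function(p, d, q, ar_coeffs = numeric(0),
                                  ma_coeffs = numeric(0), innovation_sd = 1,
                                  n, seed = 1L) {
  p <- as.integer(p); d <- as.integer(d); q <- as.integer(q)
  stopifnot(p >= 0, d >= 0, q >= 0, length(ar_coeffs) == p,
            length(ma_coeffs) == q)
  if (n <= p + q + d) stop("n must exceed p + q + d", call. = FALSE)
  if (p > 0) {
    roots <- polyroot(c(1, -ar_coeffs))
    if (any(Mod(roots) <= 1 + 1e-8)) {
      stop("AR coefficients define a non-stationary polynomial", call. = FALSE)
    }
  }
  if (q > 0) {
    roots <- polyroot(c(1, ma_coeffs))
    if (any(Mod(roots) <= 1 + 1e-8)) {
      stop("MA coefficients define a non-invertible polynomial", call. = FALSE)
    }
  }
  with_seed(seed, {
    burn <- max(10L * (p + q), 20L)
    m <- n - d + burn
    e <- stats::rnorm(m, 0, innovation_sd)
    w <- numeric(m)
    for (t in seq_len(m)) {
      ar_part <- 0
      if (p > 0) for (i in seq_len(p)) if (t - i >= 1) {
        ar_part <- ar_part + ar_coeffs[i] * w[t - i]
      }
      ma_part <- 0
      if (q > 0) for (j in seq_len(q)) if (t - j >= 1) {
        ma_part <- ma_part + ma_coeffs[j] * e[t - j]
      }
      w[t] <- ar_part + ma_part + e[t]
    }
    x <- w[(burn + 1):m]
    for (k in seq_len(d)) x <- cumsum(c(0, x))
    x[seq_len(n)]
  })
}

#' Simulate a cohort of patients with clinical covariates
#'
#' Draws per-patient covariates from stated marginal frequencies (defaults
#' mirror a typical adult moderate-to-severe TBI cohort: 78% male, median age
#' near 38 years) and simulates each patient's waveform record. Optional
#' `subgroup_effects` in the configuration add parameter offsets to affected
#' patients so subgroup comparisons have known ground truth; the supported
#' level keys are `"marshall_ge5"`, `"marshall_lt5"`, `"sex_M"`, `"sex_F"`,
#' `"hypoxia_yes"`, `"hypotension_yes"`, `"age_ge40"`, `"age_lt40"`, and the
#' supported offsets are `noise_sd_scale` (multiplies every channel's
#' noise sd), `slow_wave_amp`, `map_baseline`, `icp_baseline` (additive).
#'
#' @param config A [sim_config()]; `n_patients` sets the cohort size.
#' @param male_frac,hypoxia_frac,hypotension_frac Marginal frequencies.
#' @param pupil_probs Probabilities of the three pupillary-response levels
#'   (bilateral reactive, unilateral unreactive, bilateral unreactive).
#' @param waveforms Simulate the waveform records too? `FALSE` returns only
#'   the covariate table (cheap, for calibration studies).
#' @return List with `waveforms` (list of `waveform_record`, or `NULL`) and
#'   `meta` (data.frame of patient covariates, one row per patient).
#' @export
simulate_cohort <- function(config, male_frac = 0.78, hypoxia_frac = 0.25,
                            hypotension_frac = 0.2,
                            pupil_probs = c(0.7, 0.15, 0.15),
                            waveforms = TRUE) {
  stopifnot(inherits(config, "sim_config"), config$n_patients >= 1)
  known_levels <- c("marshall_ge5", "marshall_lt5", "sex_M", "sex_F",
                    "hypoxia_yes", "hypotension_yes", "age_ge40", "age_lt40")
  bad <- setdiff(names(config$subgroup_effects), known_levels)
  if (length(bad)) {
    stop("subgroup_effects references unknown covariate level(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- config$n_patients
  meta <- with_seed(config$seed + 104729L, {
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = pmin(90, pmax(16, round(stats::qlnorm(stats::runif(n),
                                                  meanlog = log(38),
                                                  sdlog = 0.45)))),
      sex = ifelse(stats::runif(n) < male_frac, "M", "F"),
      hypoxia = ifelse(stats::runif(n) < hypoxia_frac, "yes", "no"),
      hypotension = ifelse(stats::runif(n) < hypotension_frac, "yes", "no"),
      pupils = sample(c("bilateral reactive", "unilateral unreactive",
                        "bilateral unreactive"), n, replace = TRUE,
                      prob = pupil_probs),
      marshall = sample(2:6, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  meta$age_group <- ifelse(meta$age >= 40, ">=40", "<40")
  meta$marshall_group <- ifelse(meta$marshall >= 5, ">=5", "<5")

  if (!waveforms) return(list(waveforms = NULL, meta = meta))
  wf <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- patient_config(config, meta[i, ])
    cfg_i$seed <- config$seed + 7L * i
    wf[[i]] <- simulate_waveforms(cfg_i, patient_id = meta$patient_id[i])
  }
  list(waveforms = wf, meta = meta)
}

# Apply subgroup_effects offsets matching one patient's covariates.
patient_config <- function(config, meta_row) {
  cfg <- config
  eff <- config$subgroup_effects
  applies <- function(level) {
    switch(level,
      marshall_ge5 = meta_row$marshall >= 5,
      marshall_lt5 = meta_row$marshall < 5,
      sex_M = meta_row$sex == "M",
      sex_F = meta_row$sex == "F",
      hypoxia_yes = meta_row$hypoxia == "yes",
      hypotension_yes = meta_row$hypotension == "yes",
      age_ge40 = meta_row$age >= 40,
      age_lt40 = meta_row$age < 40,
      FALSE)
  }
  for (level in names(eff)) {
    if (!applies(level)) next
    off <- eff[[level]]
    if (!is.null(off$noise_sd_scale)) cfg$noise_sd <- cfg$noise_sd * off$noise_sd_scale
    for (fld in c("slow_wave_amp", "map_baseline", "icp_baseline")) {
      if (!is.null(off[[fld]])) cfg[[fld]] <- cfg[[fld]] + off[[fld]]
    }
  }
  cfg
}

#' Write missing runs into a series
#'
#' @param series Numeric vector.
#' @param gap_spec List of `c(start_index, run_length)` pairs; runs must lie
#'   within bounds and must not overlap.
#' @return The series with exactly the requested positions set to `NA`.
#' @export
inject_gaps <- function(series, gap_spec) {
  if (!length(gap_spec)) return(series)
  spans <- validate_gap_spec(gap_spec, length(series))
  series[unlist(spans)] <- NA_real_
  series
}

#' Write a waveform record as a per-patient CSV
#'
#' One row per sample: a `time_s` column plus one column per channel; missing
#' samples become empty cells. A single `#`-prefixed comment line records the
#' patient id and sampling rate.
#' @param record A `waveform_record`.
#' @param path Output file path.
#' @export
write_waveform_csv <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  n <- length(record$channels[[1]])
  df <- data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate,
                   record$channels, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cvrarima waveform patient_id=%s sampling_rate=%g",
                     record$patient_id, record$sampling_rate), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Read a waveform CSV written by [write_waveform_csv()]
#' @param path File path.
#' @return A `waveform_record`.
#' @export
read_waveform_csv <- function(path) {
  header <- readLines(path, n = 1L)
  pid <- sub(".*patient_id=(\\S+).*", "\\1", header)
  fs <- as.numeric(sub(".*sampling_rate=(\\S+).*", "\\1", header))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  channels <- as.list(df[setdiff(names(df), "time_s")])
  structure(list(patient_id = pid, channels = lapply(channels, as.numeric),
                 sampling_rate = fs, t0 = df$time_s[1]),
            class = "waveform_record")
}
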