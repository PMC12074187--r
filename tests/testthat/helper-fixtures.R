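# Shared fixtures built in code.

# Low-noise simulator configuration: slow-wave amplitude well above channel
# noise, so coupling-sign properties are deterministic in practice.
low_noise_config <- function(seed = 3, g = 1, duration = 60) {
  sim_config(seed = seed, duration = duration, autoregulation_gain = g,
             noise_sd = c(ABP = 0.2, ICP = 0.1, rSO2_L = 0.2, rSO2_R = 0.2,
                          PbtO2 = 0.3))
}

# Pure cardiac tone ICP waveform: amplitude amp at freq Hz, fs sampling.
pure_tone <- function(amp = 2, freq = 1.2, fs = 50, minutes = 2, base = 10) {
  t <- (seq_len(fs * 60 * minutes) - 1) / fs
  base + amp * sin(2 * pi * freq * t)
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every assignment
# of ranks to group A (independent oracle for compare_two).
mw_exact_p_bruteforce <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  u_of <- function(ia) {
    ra <- rank(pooled)[ia]
    sum(ra) - length(ia) * (length(ia) + 1) / 2
  }
  u_obs <- u_of(seq_along(a))
  u_all <- apply(idx, 2, u_of)
  mu <- length(a) * length(b) / 2
  # two-sided: as or more extreme in |U - mu|
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}
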