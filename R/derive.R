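# Signal derivation: 10-s non-overlapping means, pulse amplitude by Fourier
# analysis, perfusion pressure, and the moving-correlation reactivity indices
# (PRx, PAx, RAC, RAP, COx, COx-a) at minute resolution.

#' Non-overlapping 10-second means of a waveform channel
#'
#' Averages samples in consecutive half-open frames `[t, t + 10)`. A frame
#' containing any missing sample yields `NA`; a trailing partial frame is
#' dropped.
#'
#' @param x Numeric sample vector.
#' @param sampling_rate Samples per second.
#' @param frame_s Frame length in seconds (default 10).
#' @return Numeric vector of frame means (possibly length zero).
#' @export
ten_second_means <- function(x, sampling_rate, frame_s = 10) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  spf <- round(sampling_rate * frame_s)
  if (spf < 1) stop("frame must contain at least one sample", call. = FALSE)
  n_frames <- length(x) %/% spf
  if (n_frames == 0L) return(numeric(0))
  m <- matrix(x[seq_len(n_frames * spf)], nrow = spf)
  colMeans(m)  # NA propagates
}

#' Cardiac pulse amplitude per 10-second frame by Fourier analysis
#'
#' For each frame: remove the frame mean, take the discrete Fourier transform,
#' locate the maximal spectral magnitude inside `cardiac_band`, and report the
#' sinusoidal amplitude of that component (`2 |X_k| / N`), so a pure sinusoid
#' of amplitude A yields A. Frames containing missing samples yield `NA`.
#'
#' @param x Waveform sample vector (typically ICP).
#' @param sampling_rate Hz.
#' @param cardiac_band Two-element Hz interval searched for the cardiac peak;
#'   the default 0.66--3 Hz spans roughly 40--180 beats per minute.
#' @param frame_s Frame length in seconds.
#' @return Numeric vector, one amplitude per complete frame.
#' @export
compute_amp <- function(x, sampling_rate, cardiac_band = c(0.66, 3),
                        frame_s = 10) {
  stopifnot_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  if (cardiac_band[2] > sampling_rate / 2 || cardiac_band[1] <= 0) {
    stop("cardiac_band must lie within (0, Nyquist)", call. = FALSE)
  }
  spf <- round(sampling_rate * frame_s)
  freqs <- (seq_len(spf) - 1) / frame_s  # bin k -> (k-1)/T Hz
  in_band <- which(freqs >= cardiac_band[1] & freqs <= cardiac_band[2] &
                     freqs <= sampling_rate / 2)
  if (!length(in_band)) {
    stop("cardiac_band contains no Fourier bin at this frame length",
         call. = FALSE)
  }
  n_frames <- length(x) %/% spf
  out <- rep(NA_real_, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1) * spf + 1):(f * spf)]
    if (anyNA(seg)) next
    spec <- stats::fft(seg - mean(seg))
    out[f] <- 2 * max(Mod(spec[in_band])) / spf
  }
  out
}

#' Cerebral perfusion pressure
#'
#' Elementwise `CPP = MAP - ICP` on aligned grids; `NA` propagates.
#' @param map_series,icp_series Equal-length numeric vectors on one grid.
#' @return Numeric vector of the same length.
#' @export
compute_cpp <- function(map_series, icp_series) {
  if (length(map_series) != length(icp_series)) {
    stop("MAP and ICP series are not aligned", call. = FALSE)
  }
  map_series - icp_series
}

#' Moving Pearson correlation at minute resolution
#'
#' Correlates the most recent `window_samples` paired 10-s means, updating
#' every `update_samples` samples (defaults: 30-sample / 5-minute windows
#' updated each minute). Windows are right-aligned: the value reported at
#' minute `t` uses the 300 s ending at `t`. A window containing any `NA`, or
#' with zero variance in either input, yields `NA`. Output is clipped to
#' `[-1, 1]`.
#'
#' @param x_10s,y_10s Aligned 10-s mean series.
#' @param window_samples Window length in 10-s samples (>= 3).
#' @param update_samples Update step in 10-s samples (default 6 = 1 minute).
#' @return Numeric vector with one value per update step; updates whose window
#'   would reach before the start of the series are `NA`.
#' @export
moving_correlation <- function(x_10s, y_10s, window_samples = 30L,
                               update_samples = 6L) {
  if (length(x_10s) != length(y_10s)) {
    stop("input series are not aligned", call. = FALSE)
  }
  if (update_samples <= 0) stop("update_samples must be positive", call. = FALSE)
  if (window_samples < 3) stop("window_samples must be >= 3", call. = FALSE)
  n_updates <- length(x_10s) %/% update_samples
  out <- rep(NA_real_, n_updates)
  for (u in seq_len(n_updates)) {
    end <- u * update_samples
    if (end < window_samples) next
    idx <- (end - window_samples + 1):end
    out[u] <- safe_cor(x_10s[idx], y_10s[idx])
  }
  out
}

#' Derive the minute-by-minute table of raw means and reactivity indices
#'
#' Converts a waveform record into the canonical minute-resolution table:
#' 10-s means of each channel, pulse amplitude (AMP) from the ICP waveform,
#' `CPP = MAP - ICP`, then the moving-correlation indices
#' `PRx = corr(ICP, MAP)`, `PAx = corr(AMP, MAP)`, `RAC = corr(AMP, CPP)`,
#' `RAP = corr(AMP, ICP)`, `COx = corr(rSO2, CPP)` and
#' `COx-a = corr(rSO2, ABP)` per hemisphere. An index is emitted only when
#' both of its source channels exist; otherwise its column is all `NA`
#' (partial monitoring). Raw minute means are the mean of the minute's six
#' 10-s means (`NA` if any is missing).
#'
#' @param record A `waveform_record` with channels among
#'   `ABP, ICP, rSO2_L, rSO2_R, PbtO2`.
#' @param cardiac_band Hz interval passed to [compute_amp()].
#' @param window_samples,update_samples Moving-correlation geometry.
#' @return A `minute_table`: data.frame with column `minute` plus the signal
#'   columns `MAP, ICP, CPP, AMP, PRx, PAx, RAC, RAP, COx_L, COx_R, COx-a_L,
#'   COx-a_R, rSO2_L, rSO2_R, PbtO2`; attribute `patient_id`.
#' @export
derive_indices <- function(record, cardiac_band = c(0.66, 3),
                           window_samples = 30L, update_samples = 6L) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$sampling_rate
  ch <- record$channels
  have <- function(nm) nm %in% names(ch) && !all(is.na(ch[[nm]]))

  ts10 <- list()
  if (have("ABP")) ts10$MAP <- ten_second_means(ch$ABP, fs)
  if (have("ICP")) {
    ts10$ICP <- ten_second_means(ch$ICP, fs)
    ts10$AMP <- compute_amp(ch$ICP, fs, cardiac_band)
  }
  for (nm in c("rSO2_L", "rSO2_R", "PbtO2")) {
    if (have(nm)) ts10[[nm]] <- ten_second_means(ch[[nm]], fs)
  }
  if (!length(ts10)) stop("record has no usable channels", call. = FALSE)
  n10 <- min(lengths(ts10))
  ts10 <- lapply(ts10, function(v) v[seq_len(n10)])
  if (!is.null(ts10$MAP) && !is.null(ts10$ICP)) {
    ts10$CPP <- compute_cpp(ts10$MAP, ts10$ICP)
  }

  n_min <- n10 %/% update_samples
  minute_mean <- function(v) {
    colMeans(matrix(v[seq_len(n_min * update_samples)], nrow = update_samples))
  }
  movc <- function(a, b) {
    if (is.null(ts10[[a]]) || is.null(ts10[[b]])) return(rep(NA_real_, n_min))
    moving_correlation(ts10[[a]], ts10[[b]], window_samples, update_samples)[seq_len(n_min)]
  }

  out <- data.frame(minute = seq_len(n_min))
  for (nm in c("MAP", "ICP", "CPP", "AMP")) {
    out[[nm]] <- if (is.null(ts10[[nm]])) rep(NA_real_, n_min) else minute_mean(ts10[[nm]])
  }
  out$PRx <- movc("ICP", "MAP")
  out$PAx <- movc("AMP", "MAP")
  out$RAC <- movc("AMP", "CPP")
  out$RAP <- movc("AMP", "ICP")
  out[["COx_L"]] <- movc("rSO2_L", "CPP")
  out[["COx_R"]] <- movc("rSO2_R", "CPP")
  out[["COx-a_L"]] <- movc("rSO2_L", "MAP")
  out[["COx-a_R"]] <- movc("rSO2_R", "MAP")
  for (nm in c("rSO2_L", "rSO2_R", "PbtO2")) {
    out[[nm]] <- if (is.null(ts10[[nm]])) rep(NA_real_, n_min) else minute_mean(ts10[[nm]])
  }
  attr(out, "patient_id") <- record$patient_id
  class(out) <- c("minute_table", "data.frame")
  out
}

#' Signal columns of a minute table
#' @param table A `minute_table` or compatible data.frame.
#' @return Character vector of signal column names present.
#' @export
minute_signals <- function(table) {
  setdiff(names(table), "minute")
}
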