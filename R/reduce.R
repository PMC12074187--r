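# Resolution reduction: the gap rule (interpolate short runs, split on long
# runs) and the non-overlapping resolution ladder from 1 min to 24 h.

#' The supported temporal resolution ladder, in minutes
#' @export
resolution_ladder <- function() {
  c(1, 5, 10, 30, 60, 120, 180, 240, 300, 360, 720, 1440)
}

#' Apply the gap rule to a minute-resolution series
#'
#' Missing runs of at most `max_fill` consecutive points are replaced by
#' linear interpolation between the flanking observed values. Longer runs
#' split the series into separate contiguous segments (concatenating across a
#' long gap would fabricate temporal adjacency). Leading and trailing missing
#' runs are trimmed: no extrapolation.
#'
#' @param x Numeric 1-min series, `NA` = missing.
#' @param max_fill Longest missing run that is interpolated (default 4, i.e.
#'   runs of five or more are excluded).
#' @return List with `values` (the input with short runs filled; long runs
#'   still `NA`), `segment_id` (integer vector, `NA` outside any segment), and
#'   `segments` (data.frame `segment_id, start, end, length`). An all-missing
#'   series yields zero segments.
#' @examples
#' fill_gaps(c(1, NA, NA, NA, 5))$values
#' @export
fill_gaps <- function(x, max_fill = 4L) {
  n <- length(x)
  values <- as.numeric(x)
  if (n == 0L || all(is.na(values))) {
    return(list(values = values, segment_id = rep(NA_integer_, n),
                segments = data.frame(segment_id = integer(0),
                                      start = integer(0), end = integer(0),
                                      length = integer(0))))
  }
  runs <- na_runs(values)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[i]; len <- runs$length[i]; e <- s + len - 1L
      interior <- s > 1L && e < n
      if (interior && len <= max_fill) {
        values[s:e] <- stats::approx(c(s - 1L, e + 1L),
                                     values[c(s - 1L, e + 1L)],
                                     xout = s:e)$y
      }
    }
  }
  # remaining NA runs (long interior runs + leading/trailing) delimit segments
  seg_id <- rep(NA_integer_, n)
  obs <- !is.na(values)
  r <- rle(obs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- 0L
  seg_rows <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    k <- k + 1L
    seg_id[starts[i]:ends[i]] <- k
    seg_rows[[k]] <- data.frame(segment_id = k, start = starts[i],
                                end = ends[i], length = r$lengths[i])
  }
  list(values = values, segment_id = seg_id,
       segments = do.call(rbind, seg_rows))
}

#' Downsample a series to a coarser resolution by non-overlapping block means
#'
#' Within each contiguous segment, consecutive blocks of
#' `target_resolution / base_resolution` points are averaged. A block is
#' emitted only when at least `min_frac` of its expected points are observed
#' (default 50%), otherwise `NA`; a trailing partial block is dropped.
#'
#' @param x Numeric series at `base_resolution`, or the list returned by
#'   [fill_gaps()].
#' @param target_resolution Target spacing in minutes; must be on the
#'   resolution ladder unless `allow_off_ladder = TRUE`, and must be a
#'   multiple of `base_resolution`.
#' @param base_resolution Input spacing in minutes (default 1).
#' @param min_frac Minimum fraction of observed points per emitted block.
#' @param allow_off_ladder Permit targets not on [resolution_ladder()].
#' @return data.frame with columns `segment_id`, `block` (index within
#'   segment), `time` (start minute of the block on the original grid), and
#'   `value`.
#' @export
downsample <- function(x, target_resolution, base_resolution = 1,
                       min_frac = 0.5, allow_off_ladder = FALSE) {
  if (!allow_off_ladder && !(target_resolution %in% resolution_ladder())) {
    stop("target_resolution is not on the resolution ladder", call. = FALSE)
  }
  if (target_resolution %% base_resolution != 0) {
    stop("base resolution must divide the target resolution", call. = FALSE)
  }
  if (is.list(x) && !is.data.frame(x)) {
    values <- x$values; seg_id <- x$segment_id
  } else {
    values <- as.numeric(x)
    seg_id <- rep(1L, length(values))
    seg_id[is.na(values) & !is.finite(values)] <- 1L
  }
  k <- as.integer(target_resolution / base_resolution)
  rows <- list()
  for (s in unique(seg_id[!is.na(seg_id)])) {
    idx <- which(seg_id == s)
    n_blocks <- length(idx) %/% k
    if (n_blocks == 0L) next
    v <- values[idx[seq_len(n_blocks * k)]]
    m <- matrix(v, nrow = k)
    n_obs <- colSums(!is.na(m))
    means <- ifelse(n_obs >= min_frac * k, colMeans(m, na.rm = TRUE), NA_real_)
    means[n_obs == 0L] <- NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      segment_id = s, block = seq_len(n_blocks),
      time = (idx[seq(1, n_blocks * k, by = k)] - 1L) * base_resolution,
      value = means)
  }
  if (!length(rows)) {
    return(data.frame(segment_id = integer(0), block = integer(0),
                      time = numeric(0), value = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Is a series long enough for downstream analysis?
#'
#' Cells failing this check are labelled `NA` and excluded downstream.
#' Defaults: 30 observed points for stationarity testing, 50 for the ARIMA
#' grid search.
#'
#' @param x Numeric vector (or `value` column of a downsampled series).
#' @param min_points Minimum number of non-missing points (inclusive).
#' @return `TRUE` if usable.
#' @export
sufficiency_check <- function(x, min_points = 30L) {
  sum(!is.na(x)) >= min_points
}

#' Longest contiguous segment after gap handling
#'
#' Convenience accessor used by the pipeline: fits are run on the longest
#' segment by default.
#' @param filled List returned by [fill_gaps()].
#' @return Numeric vector (possibly length zero).
#' @export
longest_segment <- function(filled) {
  seg <- filled$segments
  if (!nrow(seg)) return(numeric(0))
  best <- seg[which.max(seg$length), ]
  filled$values[best$start:best$end]
}
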