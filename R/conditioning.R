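#' Z-score the columns of a time-course table
#'
#' Standardizes every network time course to mean 0, standard deviation 1
#' (population convention, i.e. the 1/N denominator), the per-recording
#' normalization applied before windowed connectivity.
#'
#' @param table a [time_course_table()] or plain numeric matrix.
#' @return same type as the input, columns standardized.
#' @export
zscore_columns <- function(table) {
  is_tct <- inherits(table, "time_course_table")
  x <- if (is_tct) table$values else as.matrix(table)
  s <- sqrt(colMeans(sweep(x, 2, colMeans(x))^2))
  bad <- which(s == 0)
  if (length(bad)) {
    stop(sprintf("cannot z-score constant column(s): %s",
                 paste(colnames(x)[bad] %||% bad, collapse = ", ")), call. = FALSE)
  }
  out <- scale_population(x)
  colnames(out) <- colnames(x)
  if (is_tct) {
    table$values <- out
    table
  } else {
    out
  }
}

#' Despike a time course by running-median replacement
#'
#' Samples deviating more than `z_threshold` robust standard deviations
#' (1.4826 x the median absolute deviation of the residuals) from the running
#' median over a +/- `half_window` frame neighborhood are replaced by that
#' running median; all other samples are untouched.
#'
#' @param series numeric vector.
#' @param z_threshold spike threshold in robust-SD multiples.
#' @param half_window half-width of the running-median window (frames).
#' @return despiked series of the same length.
#' @export
despike <- function(series, z_threshold = 4, half_window = 5) {
  stop_if_not(half_window >= 1, "half_window must be >= 1")
  stop_if_not(z_threshold > 0, "z_threshold must be > 0")
  width <- 2L * as.integer(half_window) + 1L
  stop_if_not(length(series) >= width,
              "series must be at least 2*half_window + 1 samples long")
  med <- runmed(series, k = width, endrule = "median")
  resid <- series - med
  robust_sd <- 1.4826 * median(abs(resid - median(resid)))
  if (robust_sd == 0) return(series)
  spikes <- abs(resid) > z_threshold * robust_sd
  series[spikes] <- med[spikes]
  series
}

# zero-phase filtering with odd-reflection padding at both ends, so edge
# transients from the filter's zero initial conditions land in the discarded
# pad rather than the data
butter_filtfilt <- function(series, filt) {
  n <- length(series)
  np <- min(n - 1, 100)
  if (np < 1) return(series)
  left <- 2 * series[1] - series[(np + 1):2]
  right <- 2 * series[n] - series[(n - 1):(n - np)]
  padded <- as.numeric(signal::filtfilt(filt, c(left, series, right)))
  padded[(np + 1):(np + n)]
}

#' Zero-phase low-pass filter
#'
#' 5th-order Butterworth applied forward and backward (zero phase). At the
#' default cutoff of 0.15 Hz with TR = 2 s, a 0.05 Hz sinusoid retains at
#' least 95% of its amplitude while a 0.22 Hz sinusoid is attenuated to at
#' most 20%.
#'
#' @param series numeric vector.
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist `1/(2*tr)`.
#' @param tr repetition time in seconds.
#' @param order Butterworth order.
#' @return filtered series, same length.
#' @export
lowpass <- function(series, cutoff_hz = 0.15, tr = 2, order = 5) {
  nyquist <- 1 / (2 * tr)
  stop_if_not(cutoff_hz > 0 && cutoff_hz < nyquist,
              "cutoff (%g Hz) must be in (0, Nyquist = %g Hz)", cutoff_hz, nyquist)
  butter_filtfilt(series, signal::butter(order, cutoff_hz / nyquist, type = "low"))
}

#' Zero-phase band-pass filter
#'
#' Band-pass between `low_hz` and `high_hz` as a cascade of a Butterworth
#' high-pass and low-pass, each applied forward-backward (zero phase), on the
#' demeaned series; the DC component is removed exactly. The cascade is
#' numerically better behaved than a single high-order band-pass
#' transfer function at narrow fractional bandwidths. Provided for parity
#' with real-data preprocessing; not applied to synthetic data by default.
#'
#' @param series numeric vector.
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < Nyquist`.
#' @param tr repetition time in seconds.
#' @param order Butterworth order (per edge).
#' @return filtered series, same length.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1, tr = 2, order = 5) {
  nyquist <- 1 / (2 * tr)
  stop_if_not(low_hz > 0 && low_hz < high_hz && high_hz < nyquist,
              "band edges must satisfy 0 < low < high < Nyquist = %g Hz", nyquist)
  x <- series - mean(series)
  x <- butter_filtfilt(x, signal::butter(order, low_hz / nyquist, type = "high"))
  butter_filtfilt(x, signal::butter(order, high_hz / nyquist, type = "low"))
}

#' Sliding-window mean of a series
#'
#' Mean over frames `[s, s + window - 1]` for starts `s = 1 .. T - window`:
#' the same window-count convention as the windowed-connectivity series, so
#' smoothed values align index-for-index with connectivity windows (297
#' frames with a 30-frame window give 267 values).
#'
#' @param series numeric vector of length `T`.
#' @param window window length in frames.
#' @return numeric vector of length `T - window`.
#' @export
sliding_mean <- function(series, window = 30) {
  n <- length(series)
  stop_if_not(n > window, "series length must exceed the window")
  cs <- c(0, cumsum(series))
  starts <- seq_len(n - window)
  (cs[starts + window] - cs[starts]) / window
}

#' Condition a recording's time courses
#'
#' Applies, per network, the standard conditioning chain used before
#' windowing: despiking, zero-phase low-pass filtering below `cutoff_hz`
#' (optionally a 0.01-0.1 Hz band-pass instead), then column z-scoring.
#'
#' @param table a [time_course_table()].
#' @param despike_series apply [despike()]?
#' @param filter `"lowpass"` (default), `"bandpass"`, or `"none"`.
#' @param cutoff_hz low-pass cutoff (Hz).
#' @return conditioned [time_course_table()].
#' @export
condition_recording <- function(table, despike_series = TRUE,
                                filter = c("lowpass", "bandpass", "none"),
                                cutoff_hz = 0.15) {
  filter <- match.arg(filter)
  x <- table$values
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (despike_series) col <- despike(col)
    col <- switch(filter,
                  lowpass = lowpass(col, cutoff_hz = cutoff_hz, tr = table$tr),
                  bandpass = bandpass(col, tr = table$tr),
                  none = col)
    x[, j] <- col
  }
  table$values <- x
  zscore_columns(table)
}
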