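#' Discrete Fourier periodogram of a time course
#'
#' One-sided periodogram on `[0, Nyquist]`, normalized so that the total
#' power equals the series' population variance (Parseval). The series is
#' demeaned first, so the DC bin carries no power.
#'
#' @param series numeric vector, length >= 8.
#' @param tr sampling interval in seconds.
#' @return `list(frequencies = <Hz>, power = <numeric>)`.
#' @export
periodogram <- function(series, tr = 2) {
  n <- length(series)
  stop_if_not(n >= 8, "series too short for a periodogram (need >= 8 samples)")
  x <- series - mean(series)
  spec <- Mod(fft(x))^2 / n^2
  m <- floor(n / 2)
  power <- spec[1:(m + 1)]
  # fold negative frequencies onto positive ones (Nyquist bin of even n and
  # DC have no mirror image)
  fold <- 2:(if (n %% 2 == 0) m else m + 1)
  power[fold] <- power[fold] + spec[n + 2 - fold]
  list(frequencies = (0:m) / (n * tr), power = power)
}

#' Fraction of spectral power below a cutoff frequency
#'
#' The screening statistic: fraction of total power at frequencies strictly
#' below `cutoff_hz`. A flat (white-noise) spectrum at TR = 2 s gives about
#' 0.4 at the default 0.1 Hz cutoff (0.1 / 0.25 of the band); a component
#' with a clear low-frequency peak gives values near 1.
#'
#' @param frequencies,power as returned by [periodogram()].
#' @param cutoff_hz cutoff in Hz, inside `(0, Nyquist)`.
#' @return fraction in `[0, 1]`.
#' @export
low_freq_ratio <- function(frequencies, power, cutoff_hz = 0.1) {
  nyquist <- max(frequencies)
  stop_if_not(cutoff_hz > 0 && cutoff_hz < nyquist,
              "cutoff must be inside (0, Nyquist = %g Hz)", nyquist)
  total <- sum(power)
  stop_if_not(total > 0, "zero total power: constant series has no spectrum")
  sum(power[frequencies < cutoff_hz]) / total
}

#' Screen components into signal vs. noise by their frequency spectrum
#'
#' Operationalizes the rule that a neuronal signal component shows a clear
#' spectral peak below 0.1 Hz while noise components have a flat spectrum:
#' a component is a signal if its low-frequency power fraction is at least
#' `threshold` (default 0.6, leaving margin on both sides of the white-noise
#' value 0.4 at TR = 2 s).
#'
#' @param tables a [time_course_table()] (each column a component) or a list
#'   of them (concatenated column-wise).
#' @param tr sampling interval in seconds (taken from the table if absent).
#' @param threshold minimum low-frequency power fraction for a signal verdict.
#' @param cutoff_hz low-frequency cutoff in Hz.
#' @return data.frame with columns `component`, `low_freq_ratio`, `verdict`.
#' @export
screen_components <- function(tables, tr = NULL, threshold = 0.6, cutoff_hz = 0.1) {
  if (inherits(tables, "time_course_table")) tables <- list(tables)
  stop_if_not(length(tables) >= 1, "need at least one component table")
  x <- do.call(cbind, lapply(tables, function(tb) tb$values))
  tr <- tr %||% tables[[1]]$tr
  ratios <- apply(x, 2, function(col) {
    pg <- periodogram(col, tr = tr)
    low_freq_ratio(pg$frequencies, pg$power, cutoff_hz = cutoff_hz)
  })
  data.frame(component = colnames(x) %||% seq_len(ncol(x)),
             low_freq_ratio = as.numeric(ratios),
             verdict = ifelse(ratios >= threshold, "signal", "noise"),
             row.names = NULL, stringsAsFactors = FALSE)
}
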