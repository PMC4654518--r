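# Analytic signal with linear-predictive edge extension: the FFT-based
# Hilbert transform assumes periodicity, so raw record edges distort the
# instantaneous phase/amplitude over the first and last cycle; extending by
# AR prediction and cropping removes that.
analytic_signal_ext <- function(x, ts = 1, pad = NULL) {
  n <- length(x)
  pad <- pad %||% min(n, 128L)
  xe <- ar_extend(x, pad, ts)
  analytic_signal(xe)[pad + seq_len(n)]
}

# Analytic signal via FFT: x + i * H[x] with the one-sided spectrum doubled.
analytic_signal <- function(x) {
  n <- length(x)
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[c(1, n / 2 + 1)] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1] <- 1
    mult[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * mult, inverse = TRUE) / n
}

#' Cycle-by-cycle periods and amplitudes from the analytic signal
#'
#' Computes the instantaneous phase of a (band-filtered, zero-mean) trace via
#' the Hilbert transform and locates the upward crossings of phase zero.
#' Successive crossing intervals give per-cycle periods; the analytic-signal
#' magnitude at each cycle's midpoint gives per-cycle amplitudes (the
#' envelope away from cycle boundaries, where transient interpolation of the
#' envelope cannot bias it). Crossing times are linearly interpolated
#' between samples.
#'
#' @param data Data frame with `time` and `value` columns (one trace).
#' @return A list with `periods` (hours), `amplitudes`, and `crossings`
#'   (interpolated crossing times, hours).
#' @export
cycle_statistics <- function(data) {
  x <- series_value(data)
  check_series_values(x, n_min = 8)
  t <- series_time(data)
  z <- analytic_signal_ext(x, t[2] - t[1])
  ph <- Arg(z)
  n <- length(ph)
  up <- which(ph[-n] < 0 & ph[-1] >= 0 & (ph[-1] - ph[-n]) < pi)
  if (length(up) < 2) abort("fewer than 2 phase zero-crossings found.")
  frac <- -ph[up] / (ph[up + 1] - ph[up])
  crossings <- t[up] + frac * (t[up + 1] - t[up])
  periods <- diff(crossings)
  amp <- vapply(seq_len(length(up) - 1), function(k) {
    Mod(z[round((up[k] + up[k + 1]) / 2)])
  }, numeric(1))
  list(periods = periods, amplitudes = amp, crossings = crossings)
}
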