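#' Configuration for the mixed intrinsic/extrinsic noise experiment
#'
#' Describes a population of minimal transcription-translation oscillators
#' ([toy_oscillator_model()]) in which intrinsic noise is set by the system
#' volume (larger `omega` = more deterministic cells) and extrinsic noise by
#' a normal distribution of free-running periods with SD `period_sd` (in
#' days, around a 1-day base period).
#'
#' @param n_cells Cells in the population (default 1000).
#' @param omega System volume for the stochastic simulation.
#' @param period_sd SD of free-running periods, days.
#' @param base_period Base period in hours (1 day).
#' @param duration,ts Record span and sampling interval, hours.
#' @return A list of class `"mixed_noise_config"`.
#' @export
mixed_noise_config <- function(n_cells = 1000, omega = 500, period_sd = 0,
                               base_period = 24, duration = 96, ts = 0.5) {
  stopifnot(period_sd >= 0, omega > 0, n_cells >= 1)
  structure(as.list(environment()), class = "mixed_noise_config")
}

#' Simulate a population with intrinsic and extrinsic noise
#'
#' Each cell runs the stochastic toy oscillator at volume `omega`; its
#' free-running period is drawn from `N(base_period, (24 * period_sd)^2)`
#' hours and imposed by scaling all propensities (time dilation). All cells
#' start synchronized on the deterministic limit cycle; the population mean
#' of the reporter species is returned together with the per-cell traces.
#'
#' @param config A [mixed_noise_config()].
#' @param seed Optional integer seed.
#' @return A list with `mean` (tibble `time`, `value`: reporter
#'   concentration averaged over cells), `cells` (matrix, per-cell reporter
#'   counts), `periods` (drawn per-cell periods, h) and `config`.
#' @export
simulate_mixed_population <- function(config = mixed_noise_config(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- toy_oscillator_model(volume = config$omega,
                                period_hours = config$base_period)
  periods <- rnorm(config$n_cells, config$base_period, 24 * config$period_sd)
  periods <- pmax(periods, config$base_period / 4)
  pop <- simulate_population(
    model, omega = config$omega, n_cells = config$n_cells,
    t_end = config$duration, dt_out = config$ts,
    cell_scale = config$base_period / periods, track = model$reporter
  )
  list(
    mean = tibble::tibble(time = pop$mean$time,
                          value = pop$mean[[model$reporter]]),
    cells = pop$cells,
    periods = periods,
    config = config
  )
}

#' Oscillation window (envelope) function
#'
#' Extracts the amplitude-versus-time "window" of a detrended oscillatory
#' series, either as the analytic-signal magnitude sampled at cycle
#' midpoints (`"hilbert"`) or as the absolute value at local extrema
#' (`"local_peaks"`). Plotted on a semi-log axis, an exponentially damped
#' oscillation gives a straight line whose slope is the damping rate.
#'
#' @param data Data frame with `time` and `value` (detrended, >= 3 cycles).
#' @param method `"hilbert"` or `"local_peaks"`.
#' @return A tibble with `time`, `amplitude`, `log_amplitude`; the method is
#'   attached as attribute `"method"`.
#' @export
window_function <- function(data, method = c("hilbert", "local_peaks")) {
  method <- match.arg(method)
  x <- series_value(data)
  check_series_values(x, n_min = 8)
  t <- series_time(data)
  if (method == "hilbert") {
    cs <- cycle_statistics(data)
    if (length(cs$crossings) < 3) abort("need at least 3 cycles.")
    mid <- (head(cs$crossings, -1) + tail(cs$crossings, -1)) / 2
    amp <- cs$amplitudes
    tw <- mid
  } else {
    i_max <- which(diff(sign(diff(x))) == -2) + 1
    i_min <- which(diff(sign(diff(x))) == 2) + 1
    idx <- sort(c(i_max, i_min))
    if (length(idx) < 3) abort("no local peaks found.")
    tw <- t[idx]
    amp <- abs(x[idx])
  }
  keep <- amp > 0
  out <- tibble::tibble(time = tw[keep], amplitude = amp[keep],
                        log_amplitude = log(amp[keep]))
  attr(out, "method") <- method
  out
}

#' Linear versus quadratic log-envelope discrimination
#'
#' Fits the log window function with a line (`log A ~ t`: exponential
#' envelope, the signature of phase diffusion / intrinsic noise) and with a
#' quadratic (`log A ~ t + t^2`: Gaussian envelope, the signature of
#' period heterogeneity / extrinsic noise). The small-amplitude tail, where
#' measurement noise dominates as the oscillation approaches steady state,
#' is excluded. The preferred shape is decided by the quadratic coefficient:
#' it must be statistically significant (t-test at `alpha`) *and*
#' materially large (the quadratic term must account for at least 5% of the
#' total log-amplitude excursion over the window, so that vanishing but
#' ultra-low-variance curvature on near-noiseless data does not flip the
#' call). Both fits are returned regardless.
#'
#' @param window A [window_function()] result.
#' @param min_rel_amplitude Drop window points below this fraction of the
#'   initial amplitude (default 0.05).
#' @param alpha Significance level for the curvature test.
#' @return A list with `linear` (slope, intercept, se), `quadratic`
#'   (coefficients), `curvature` (estimate, p-value), `preferred`
#'   (`"exponential"` or `"gaussian"`), `damping` (minus the linear slope),
#'   and `n_points`.
#' @export
envelope_shape_fit <- function(window, min_rel_amplitude = 0.05,
                               alpha = 0.05) {
  a0 <- window$amplitude[1]
  keep <- window$amplitude >= min_rel_amplitude * a0
  w <- window[keep, ]
  if (nrow(w) < 5) abort("fewer than 5 window points after tail exclusion.")
  lin <- lm(log_amplitude ~ time, data = w)
  quad <- lm(log_amplitude ~ time + I(time^2), data = w)
  sq <- summary(quad)$coefficients
  curv <- sq["I(time^2)", "Estimate"]
  curv_p <- sq["I(time^2)", "Pr(>|t|)"]
  spread <- diff(range(w$log_amplitude))
  material <- abs(curv) * diff(range(w$time))^2 / 4 >= 0.05 * max(spread, 1e-12)
  list(
    linear = list(slope = coef(lin)[["time"]],
                  intercept = coef(lin)[["(Intercept)"]],
                  slope_se = summary(lin)$coefficients["time", "Std. Error"]),
    quadratic = list(coef = coef(quad)),
    curvature = list(estimate = curv, p_value = curv_p),
    preferred = if (is.finite(curv_p) && curv_p < alpha && material)
      "gaussian" else "exponential",
    damping = -coef(lin)[["time"]],
    n_points = nrow(w)
  )
}
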