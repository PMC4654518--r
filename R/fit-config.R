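#' Configuration for damped-sinusoid fitting
#'
#' Collects the tunable parameters of the fitting pipeline. Defaults follow
#' standard practice for circadian bioluminescence records: a Hodrick-Prescott
#' smoothing parameter tied to the sampling rate, a fifth-order Butterworth
#' low-pass at 0.1 of Nyquist, a matrix-pencil parameter of one third of the
#' record length, model order selected from the normalized singular values,
#' and a circadian period window of 6-50 h for mode selection.
#'
#' @param hp_gamma Hodrick-Prescott smoothing parameter, or `"auto"` for
#'   `0.05 * (24 / ts)^4`.
#' @param butterworth_order Low-pass filter order.
#' @param butterworth_cutoff Low-pass cutoff as a fraction of Nyquist, in (0,1).
#' @param pencil_parameter Matrix-pencil parameter `L`, or `NULL` for
#'   `floor(N / 3)`.
#' @param model_order Number of exponential modes, or `NULL` to keep singular
#'   values above `sv_tol` times the largest (capped at `max_order`).
#' @param sv_tol Normalized singular-value threshold for automatic model-order
#'   selection.
#' @param max_order Cap on the automatically selected model order.
#' @param period_window Two-element numeric: admissible period range (hours)
#'   for the reported circadian mode.
#' @param refine Logical: polish the matrix-pencil `(d, T)` estimate by
#'   minimizing the matched-basis residual (see [fit_damped_sinusoid()]).
#'   Default `TRUE`; batch pipelines may disable it for speed.
#'
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(hp_gamma = "auto",
                       butterworth_order = 5,
                       butterworth_cutoff = 0.1,
                       pencil_parameter = NULL,
                       model_order = NULL,
                       sv_tol = 1e-3,
                       max_order = 6,
                       period_window = c(6, 50),
                       refine = TRUE) {
  stopifnot(length(period_window) == 2, period_window[1] > 0,
            period_window[2] > period_window[1],
            butterworth_cutoff > 0, butterworth_cutoff < 1)
  structure(
    list(
      hp_gamma = hp_gamma,
      butterworth_order = as.integer(butterworth_order),
      butterworth_cutoff = butterworth_cutoff,
      pencil_parameter = pencil_parameter,
      model_order = model_order,
      sv_tol = sv_tol,
      max_order = as.integer(max_order),
      period_window = as.numeric(period_window),
      refine = isTRUE(refine)
    ),
    class = "fit_config"
  )
}
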