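#' Stochastic population simulation of a reaction-network oscillator
#'
#' Converts the model to a stochastic biochemical system (propensities are
#' the deterministic rate laws evaluated on concentrations `X / Omega`,
#' multiplied by `Omega`) and simulates `n_cells` independent oscillators,
#' all starting from identical initial conditions: a point on the
#' deterministic limit cycle with counts `round(concentration * Omega)`.
#' The population-level signal is the per-species mean across cells.
#'
#' @param model A `"reaction_model"` ([clock_model()],
#'   [toy_oscillator_model()]).
#' @param omega System volume (molecules per concentration unit); defaults
#'   to `model$volume`.
#' @param n_cells Number of independent oscillators.
#' @param t_end,dt_out Simulated span and output interval (hours).
#' @param method `"tau"` for fixed-step tau-leaping (default; step `tau`),
#'   `"exact"` for the exact direct-method SSA.
#' @param tau Tau-leap step (hours).
#' @param x0 Named initial concentrations; default: limit-cycle state from
#'   [limit_cycle()] of the *unperturbed* nominal parameters if
#'   `x0_model` is given, else of `model` itself.
#' @param x0_model Optional model whose limit cycle supplies the initial
#'   state (used by knockdown scans: cells are entrained before the
#'   perturbation applies).
#' @param cell_scale Per-cell rate multiplier (length 1 or `n_cells`):
#'   cell `i` runs with all propensities scaled by `cell_scale[i]`, which
#'   rescales its free-running period by `1 / cell_scale[i]`.
#' @param track Optional species name: return that species' per-cell count
#'   trajectories as well.
#' @param seed Optional integer seed.
#' @return An object of class `"population_result"`: list with `mean` (a
#'   tibble: `time` plus one concentration column per species), `omega`,
#'   `n_cells`, `model`, and optionally `cells` (matrix, per-cell counts of
#'   the tracked species).
#' @export
simulate_population <- function(model, omega = model$volume, n_cells = 100,
                                t_end = 120, dt_out = 0.5,
                                method = c("tau", "exact"), tau = 0.05,
                                x0 = NULL, x0_model = NULL,
                                cell_scale = 1, track = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (omega <= 0) abort("`omega` must be positive.")
  if (is.null(x0)) {
    x0 <- limit_cycle(x0_model %||% model)$state
  }
  x0 <- x0[model$species]
  track_idx <- if (is.null(track)) 0L else match(track, model$species)
  if (!is.null(track) && is.na(track_idx)) abort("unknown `track` species.")
  res <- simulate_cells_cpp(
    model$id, unname(model$params), omega, unname(round(x0 * omega)),
    t_end, dt_out, as.integer(n_cells), tau,
    as.numeric(cell_scale), method == "exact", as.integer(track_idx)
  )
  mean_conc <- res$mean / omega
  colnames(mean_conc) <- model$species
  out <- list(
    mean = dplyr::bind_cols(
      tibble::tibble(time = seq(0, by = dt_out,
                                length.out = nrow(mean_conc))),
      tibble::as_tibble(mean_conc)
    ),
    omega = omega, n_cells = n_cells, model = model,
    cells = if (!is.null(track)) res$cells else NULL,
    dt_out = dt_out
  )
  class(out) <- "population_result"
  out
}

#' @export
print.population_result <- function(x, ...) {
  cat("Stochastic population:", x$n_cells, "cells, Omega =", x$omega, "\n")
  cat("  span:", max(x$mean$time), "h at dt =", x$dt_out, "h\n")
  invisible(x)
}

#' Fit population-level damping from a stochastic simulation
#'
#' Fits a damped sinusoid to the population mean of every state variable,
#' pools the goodness of fit over all states (`pooled R^2 = 1 - total
#' residual SS / total centered SS`, both computed on the detrended means),
#' and reports the damping rate and period of the model's reporter state.
#' Simulations with pooled `R^2` below `r2_min` are marked not accepted
#' (too noise-dominated for the damping rate to be meaningful).
#'
#' @param result A `"population_result"`.
#' @param r2_min Acceptance threshold on the pooled `R^2` (default 0.90).
#' @param config Fit configuration. The reporter state, which supplies the
#'   reported `(d, T)`, is fit with matched-model refinement (halves the
#'   replicate-to-replicate variance of the damping estimate); the remaining
#'   states use the fast matrix-pencil path, since they only enter the
#'   pooled goodness of fit.
#' @return A list with `damping`, `period` (reporter state), `pooled_r2`,
#'   `accepted`, and `fits` (tibble of per-state parameters).
#' @export
fit_population_damping <- function(result, r2_min = 0.90,
                                   config = fit_config(refine = FALSE)) {
  mean_df <- result$mean
  species <- result$model$species
  rows <- list()
  rss <- 0
  tss <- 0
  for (sp in species) {
    cfg_sp <- config
    if (sp == result$model$reporter) cfg_sp$refine <- TRUE
    f <- tryCatch(
      fit_damped_sinusoid(tibble::tibble(time = mean_df$time,
                                         value = mean_df[[sp]]), cfg_sp),
      error = function(e) NULL
    )
    if (is.null(f)) {
      if (sp == result$model$reporter) {
        abort(sprintf("fit failed on reporter state '%s'.", sp))
      }
      next
    }
    res <- f$data$detrended - f$data$fitted
    rss <- rss + sum(res^2)
    tss <- tss + sum((f$data$detrended - mean(f$data$detrended))^2)
    rows[[sp]] <- tibble::tibble(
      species = sp, amplitude = f$amplitude, damping = f$damping,
      period = f$period, phase = f$phase, r_squared = f$r_squared
    )
  }
  fits <- dplyr::bind_rows(rows)
  pooled <- if (tss > 0) 1 - rss / tss else -Inf
  rep_row <- fits[fits$species == result$model$reporter, ]
  list(
    damping = rep_row$damping, period = rep_row$period,
    pooled_r2 = pooled, accepted = pooled >= r2_min, fits = fits
  )
}

#' Calibrate the system volume against an observed damping rate
#'
#' Simulates replicate populations across a logarithmic grid of volumes,
#' fits the population damping rate at each volume, performs a weighted
#' linear regression of `log d` on `log Omega` (weights `1 / SE(log d)^2`,
#' using the per-volume SEM over replicates), and inverts the line at the
#' target damping rate. Replicates whose pooled `R^2` falls below `r2_min`
#' are excluded, as are grid points with fewer than two surviving
#' replicates.
#'
#' @param model A `"reaction_model"`.
#' @param target_d Observed population damping rate to match (1/h; > 0).
#' @param omega_range Range (low, high) of volumes to scan.
#' @param n_grid Number of log-spaced grid points.
#' @param n_reps Replicate populations per grid point.
#' @param n_cells Cells per population.
#' @param t_end,dt_out,tau,method Passed to [simulate_population()].
#' @param r2_min Pooled-R^2 acceptance threshold.
#' @param seed Optional integer seed.
#' @return An object of class `"calibration_curve"`: list with `grid` (a
#'   tibble: `omega`, `d_mean`, `d_sem`, `r2_mean`, `n_ok`, `used`),
#'   `slope`, `intercept`, `fitted_omega`, `fitted_omega_se`,
#'   `target_d`, `extrapolated`, `regression` (the `lm` fit on the log-log
#'   scale).
#' @export
calibrate_volume <- function(model, target_d = 0.0151,
                             omega_range = c(100, 500), n_grid = 15,
                             n_reps = 10, n_cells = 1000,
                             t_end = 120, dt_out = 0.5, tau = 0.05,
                             method = "tau", r2_min = 0.90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (target_d <= 0) abort("`target_d` must be positive.")
  omegas <- exp(seq(log(omega_range[1]), log(omega_range[2]),
                    length.out = n_grid))
  x0 <- limit_cycle(model)$state
  rows <- purrr::map(omegas, function(om) {
    ds <- numeric(0)
    r2s <- numeric(0)
    for (r in seq_len(n_reps)) {
      pop <- simulate_population(model, omega = om, n_cells = n_cells,
                                 t_end = t_end, dt_out = dt_out,
                                 method = method, tau = tau, x0 = x0)
      ft <- fit_population_damping(pop, r2_min = r2_min)
      r2s <- c(r2s, ft$pooled_r2)
      if (ft$accepted && ft$damping > 0) ds <- c(ds, ft$damping)
    }
    tibble::tibble(
      omega = om, d_mean = mean(ds), d_sem = sd(ds) / sqrt(length(ds)),
      r2_mean = mean(r2s), n_ok = length(ds),
      used = length(ds) >= 2
    )
  }) |> dplyr::bind_rows()

  used <- rows[rows$used, ]
  if (nrow(used) < 3) abort("fewer than 3 usable volume grid points; widen the grid or increase replicates.")
  se_log <- used$d_sem / used$d_mean
  se_log[se_log <= 0 | !is.finite(se_log)] <- max(se_log[is.finite(se_log) & se_log > 0], 1e-3)
  # with few replicates the SEM estimates are themselves noisy; flooring
  # them at their median stops an accidentally tiny SEM from dominating
  se_log <- pmax(se_log, median(se_log))
  reg <- lm(log(d_mean) ~ log(omega), data = used, weights = 1 / se_log^2)
  sl <- coef(reg)[["log(omega)"]]
  ic <- coef(reg)[["(Intercept)"]]
  fitted_omega <- exp((log(target_d) - ic) / sl)
  # delta-method SE from the coefficient covariance
  vc <- stats::vcov(reg)
  lo <- (log(target_d) - ic) / sl
  grad <- c(-1 / sl, -lo / sl)           # d lo / d(ic), d lo / d(sl)
  se_lo <- sqrt(drop(t(grad) %*% vc %*% grad))
  extrap <- target_d < min(used$d_mean) || target_d > max(used$d_mean)
  if (extrap) {
    warn("target damping rate lies outside the simulated range; the fitted volume is an extrapolation.")
  }
  structure(
    list(
      grid = rows, slope = sl, intercept = ic,
      slope_se = sqrt(vc[2, 2]),
      fitted_omega = fitted_omega,
      fitted_omega_se = fitted_omega * se_lo,
      target_d = target_d, extrapolated = extrap, regression = reg
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Volume calibration: log d ~ log Omega\n")
  cat(sprintf("  slope = %.3f (SE %.3f), intercept = %.3f\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("  fitted Omega = %.1f +/- %.1f at target d = %.4g /h%s\n",
              x$fitted_omega, x$fitted_omega_se, x$target_d,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    fitted_omega = x$fitted_omega, fitted_omega_se = x$fitted_omega_se,
    slope = x$slope, intercept = x$intercept, target_d = x$target_d,
    r.squared = summary(x$regression)$r.squared,
    n_points = sum(x$grid$used), extrapolated = x$extrapolated
  )
}

#' @export
tidy.calibration_curve <- function(x, ...) x$grid

#' Plot a volume-calibration curve
#'
#' @param object A `"calibration_curve"`.
#' @param ... Unused.
#' @return A ggplot: mean damping rate (with SEM error bars) against volume
#'   on log-log axes, the weighted regression line, and the inverted target
#'   point.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$omega, y = .data$d_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$d_mean - .data$d_sem,
                                        ymax = .data$d_mean + .data$d_sem),
                           width = 0.02, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$used)) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, linetype = 2) +
    ggplot2::annotate("point", x = object$fitted_omega, y = object$target_d,
                      shape = 4, size = 3, colour = "#b2182b") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Omega), y = "damping rate d (1/h)") +
    ggplot2::theme_minimal()
}

#' Parameter knockdown scan
#'
#' Reduces one kinetic parameter over a grid of fractions of its nominal
#' value (emulating increasing doses of a small molecule) and measures the
#' population-level period and damping rate at each dose. All populations
#' start from the *nominal* entrained limit-cycle state, as cells are
#' entrained before a perturbation applies. Rows whose mean pooled `R^2`
#' falls below `r2_min` (including oscillation death at strong knockdown)
#' are flagged, not dropped.
#'
#' @param model A `"reaction_model"`.
#' @param parameter Name of the parameter to reduce (e.g. `"vdCn"`,
#'   `"vaC1P"`).
#' @param fractions Vector of fractions of the nominal value, descending
#'   from 1 (default 20 linearly spaced values from 1 to 0.15).
#' @param omega,n_reps,n_cells,t_end,dt_out,tau,method,r2_min,seed As in
#'   [calibrate_volume()].
#' @return A tibble with one row per fraction: `fraction`, `period_mean`,
#'   `period_sem`, `damping_mean`, `damping_sem`, `r2_mean`, `n_ok`,
#'   `flagged`.
#' @export
knockdown_scan <- function(model, parameter,
                           fractions = seq(1, 0.15, length.out = 20),
                           omega = model$volume, n_reps = 10, n_cells = 1000,
                           t_end = 120, dt_out = 0.5, tau = 0.05,
                           method = "tau", r2_min = 0.90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!parameter %in% names(model$params)) {
    abort(sprintf("parameter '%s' is not in the model.", parameter))
  }
  if (any(diff(fractions) > 0) || fractions[1] != 1) {
    abort("`fractions` must descend from 1.")
  }
  x0 <- limit_cycle(model)$state
  purrr::map(fractions, function(fr) {
    m <- model
    m$params[[parameter]] <- m$params[[parameter]] * fr
    m$volume <- omega
    ds <- numeric(0); ps <- numeric(0); r2s <- numeric(0)
    for (r in seq_len(n_reps)) {
      pop <- simulate_population(m, omega = omega, n_cells = n_cells,
                                 t_end = t_end, dt_out = dt_out,
                                 method = method, tau = tau, x0 = x0)
      ft <- tryCatch(fit_population_damping(pop, r2_min = r2_min),
                     error = function(e) NULL)
      if (is.null(ft)) next
      r2s <- c(r2s, ft$pooled_r2)
      if (ft$accepted) {
        ds <- c(ds, ft$damping)
        ps <- c(ps, ft$period)
      }
    }
    tibble::tibble(
      fraction = fr,
      period_mean = mean(ps), period_sem = sd(ps) / sqrt(length(ps)),
      damping_mean = mean(ds), damping_sem = sd(ds) / sqrt(length(ds)),
      r2_mean = if (length(r2s)) mean(r2s) else NA_real_,
      n_ok = length(ds), flagged = length(ds) < 2 || mean(r2s) < r2_min
    )
  }) |> dplyr::bind_rows()
}
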