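#' Generate a damped sinusoid with trend and noise
#'
#' Synthesizes `A * exp(-d t) * sin(2 pi t / T + theta)` plus an optional
#' polynomial trend and white noise, with the generating truth attached for
#' recovery studies.
#'
#' @param amplitude,damping,period,phase Generating parameters (`damping` in
#'   1/h, `period` in h, `phase` in radians).
#' @param ts Sampling interval (h).
#' @param n Number of samples.
#' @param noise_sd Standard deviation of additive white noise.
#' @param trend_coeffs Numeric vector of polynomial trend coefficients
#'   (intercept first), evaluated on time in hours.
#' @param seed Optional integer seed.
#' @return A tibble with `time` and `value`; the generating parameters are
#'   attached as attribute `"truth"`.
#' @export
generate_damped_series <- function(amplitude = 1, damping = 0.015,
                                   period = 24, phase = 0, ts = 1, n = 96,
                                   noise_sd = 0, trend_coeffs = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(amplitude >= 0, period > 0, ts > 0, n >= 4, noise_sd >= 0)
  t <- ts * (0:(n - 1))
  trend <- rowSums(sapply(seq_along(trend_coeffs),
                          function(k) trend_coeffs[k] * t^(k - 1)))
  y <- amplitude * exp(-damping * t) * sin(2 * pi * t / period + phase) +
    trend + rnorm(n, sd = noise_sd)
  out <- tibble::tibble(time = t, value = y)
  attr(out, "truth") <- list(amplitude = amplitude, damping = damping,
                             period = period, phase = phase,
                             noise_sd = noise_sd, trend_coeffs = trend_coeffs)
  out
}

#' Configuration for the synthetic single-cell population generator
#'
#' Defaults mirror the fibroblast regime of circadian single-cell reporter
#' recordings: 79 cells sampled every 0.5 h for 10 days, a ~24.2 h mean
#' period with a cell-to-cell SD of 0.89 h and a larger cycle-to-cycle SD of
#' 1.43 h, lognormal per-cycle amplitudes, white high-frequency noise and a
#' slow baseline drift. Traces start at random phases (recordings are not
#' synchronized).
#'
#' @param n_cells Number of cells.
#' @param ts Sampling interval (h).
#' @param duration Record length (h).
#' @param mean_period Population mean free-running period (h).
#' @param sd_between Cell-to-cell SD of mean periods (h).
#' @param sd_within Cycle-to-cycle period SD within a cell (h).
#' @param amplitude_mean Mean cycle amplitude (luminescence units).
#' @param amplitude_cv CV of lognormal per-cycle amplitudes.
#' @param hf_noise_sd SD of additive white noise.
#' @param drift_scale Amplitude of the slow baseline drift component.
#' @param drift_period Period of the slow drift (h; > the wavelet band upper
#'   edge so it is stripped by detrending).
#' @return A list of class `"cell_population_config"`.
#' @export
cell_population_config <- function(n_cells = 79, ts = 0.5, duration = 240,
                                   mean_period = 24.2, sd_between = 0.89,
                                   sd_within = 1.43, amplitude_mean = 1,
                                   amplitude_cv = 0.2, hf_noise_sd = 0.1,
                                   drift_scale = 0.5, drift_period = 600) {
  cfg <- as.list(environment())
  stopifnot(sd_between >= 0, sd_within >= 0, amplitude_cv >= 0,
            hf_noise_sd >= 0, n_cells >= 1, ts > 0, duration > 4 * ts)
  structure(cfg, class = "cell_population_config")
}

#' Generate synthetic single-cell bioluminescence traces
#'
#' Each cell draws a mean period from the between-cell distribution, then
#' advances phase cycle by cycle with independent Gaussian cycle-length
#' perturbations (a phase random walk at cycle resolution). Per-cycle
#' amplitudes are lognormal, interpolated linearly across the cycle; white
#' noise and a slow sinusoidal baseline drift are added, and each trace
#' starts at a uniform random phase.
#'
#' @param config A [cell_population_config()].
#' @param seed Optional integer seed.
#' @return A long tibble with `cell_id`, `time`, `value`; the per-cell truth
#'   (mean periods, realized cycle periods) is attached as attribute
#'   `"truth"`.
#' @export
generate_cell_traces <- function(config = cell_population_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, config$duration, by = config$ts)
  sdlog <- sqrt(log(1 + config$amplitude_cv^2))
  traces <- vector("list", config$n_cells)
  truth <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    t_mean <- rnorm(1, config$mean_period, config$sd_between)
    n_cyc <- ceiling(config$duration / max(4, t_mean - 4 * config$sd_within)) + 3
    periods <- pmax(4, rnorm(n_cyc, t_mean, config$sd_within))
    bounds <- c(0, cumsum(periods))
    phi0 <- runif(1, 0, 2 * pi)
    cyc <- findInterval(t, bounds)            # 1-based cycle index
    frac <- (t - bounds[cyc]) / periods[cyc]
    phase <- phi0 + 2 * pi * (cyc - 1 + frac)
    amps <- rlnorm(n_cyc + 1, log(config$amplitude_mean) - sdlog^2 / 2, sdlog)
    amp_t <- amps[cyc] + frac * (amps[cyc + 1] - amps[cyc])
    drift <- config$drift_scale *
      sin(2 * pi * t / config$drift_period + runif(1, 0, 2 * pi))
    value <- amp_t * sin(phase) + drift + rnorm(length(t), sd = config$hf_noise_sd)
    id <- sprintf("cell_%03d", i)
    traces[[i]] <- tibble::tibble(cell_id = id, time = t, value = value)
    truth[[i]] <- list(cell_id = id, mean_period = t_mean, periods = periods)
  }
  out <- dplyr::bind_rows(traces)
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}

#' Configuration for the synthetic plate-screen generator
#'
#' Emulates the statistical structure of a genome-wide siRNA circadian
#' reporter screen: wells sampled every 2 h for 72 points, a fraction of
#' no-siRNA control wells, gene-level parameter shifts shared across ~4
#' replicate wells, plate-level batch effects, and a fraction of arrhythmic
#' (noise-only) wells.
#'
#' @param n_plates Number of plates.
#' @param wells_per_plate Wells on each plate.
#' @param control_fraction Fraction of wells that carry no siRNA (controls).
#' @param replicates Wells per perturbed gene.
#' @param ts,n Sampling interval (h) and samples per well.
#' @param base_params Named list of control-population means: `period` (h),
#'   `ln_amplitude`, `damping` (1/h), `phase` (rad).
#' @param well_sd Named list of well-to-well SDs for the same four
#'   parameters.
#' @param gene_sd Named list of SDs of gene-level shifts (shared by a gene's
#'   replicates).
#' @param plate_sd Named list of SDs of plate-level additive effects (the
#'   amplitude effect is multiplicative: additive in `ln_amplitude`).
#' @param arrhythmic_fraction Fraction of perturbed wells replaced by AR(1)
#'   noise with a slow trend (no rhythm).
#' @param robust_quadrant_fraction Fraction of genes assigned a shift into
#'   the "more robust" quadrant (higher amplitude, lower damping); the
#'   remaining genes are kept out of that quadrant.
#' @param robust_shift_size Size of those shifts, in units of the well SD.
#' @param noise_sd Measurement noise SD added to every time point.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(n_plates = 8, wells_per_plate = 360,
                          control_fraction = 0.1, replicates = 4,
                          ts = 2, n = 72,
                          base_params = list(period = 24, ln_amplitude = 0,
                                             damping = 0.015, phase = 0),
                          well_sd = list(period = 0.5, ln_amplitude = 0.15,
                                         damping = 0.003, phase = 0.25),
                          gene_sd = list(period = 0.8, ln_amplitude = 0.3,
                                         damping = 0.006, phase = 0.3),
                          plate_sd = list(period = 0.3, ln_amplitude = 0.2,
                                          damping = 0.002, phase = 0.15),
                          arrhythmic_fraction = 0.05,
                          robust_quadrant_fraction = 0,
                          robust_shift_size = 4,
                          noise_sd = 0.05) {
  cfg <- as.list(environment())
  stopifnot(control_fraction > 0, control_fraction < 1, replicates >= 1,
            arrhythmic_fraction >= 0, arrhythmic_fraction < 1,
            robust_quadrant_fraction >= 0, robust_quadrant_fraction <= 1)
  structure(cfg, class = "screen_config")
}

#' Generate a synthetic plate-format screen
#'
#' @param config A [screen_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `plate_id`, `well_pos`, `gene_id`,
#'   `category` (`"control"`/`"perturbed"`), and `t0` ... `t{n-1}` holding
#'   the time courses. Attribute `"truth"` records per-well generating
#'   parameters, gene shifts, and arrhythmic flags; attribute `"times"` the
#'   sampling grid in hours.
#' @export
generate_screen <- function(config = screen_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pars <- c("period", "ln_amplitude", "damping", "phase")
  n_wells <- config$n_plates * config$wells_per_plate
  n_ctrl <- round(n_wells * config$control_fraction)
  n_pert <- n_wells - n_ctrl
  n_genes <- ceiling(n_pert / config$replicates)

  # gene-level shifts; optionally place a chosen fraction in the
  # higher-amplitude, lower-damping quadrant and keep the rest out of it
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  shift <- matrix(0, n_genes, 4, dimnames = list(gene_ids, pars))
  for (p in pars) shift[, p] <- rnorm(n_genes, 0, config$gene_sd[[p]])
  if (config$robust_quadrant_fraction > 0) {
    n_rob <- round(n_genes * config$robust_quadrant_fraction)
    rob <- seq_len(n_rob)       # first n_rob genes: forced into the quadrant
    sz <- config$robust_shift_size
    shift[rob, "ln_amplitude"] <- abs(rnorm(n_rob, sz * config$well_sd$ln_amplitude,
                                            config$well_sd$ln_amplitude / 2))
    shift[rob, "damping"] <- -abs(rnorm(n_rob, sz * config$well_sd$damping,
                                        config$well_sd$damping / 2))
    oth <- setdiff(seq_len(n_genes), rob)
    bad <- oth[shift[oth, "ln_amplitude"] > 0 & shift[oth, "damping"] < 0]
    # reflect offending genes out of the quadrant
    shift[bad, "ln_amplitude"] <- -shift[bad, "ln_amplitude"]
  }

  plate_ids <- sprintf("plate_%02d", seq_len(config$n_plates))
  plate_eff <- matrix(0, config$n_plates, 4,
                      dimnames = list(plate_ids, pars))
  for (p in pars) plate_eff[, p] <- rnorm(config$n_plates, 0, config$plate_sd[[p]])

  # assign wells: controls and gene replicates scattered across plates
  well_gene <- c(rep(NA_character_, n_ctrl),
                 rep(gene_ids, each = config$replicates)[seq_len(n_pert)])
  well_gene <- sample(well_gene)
  plate_of <- rep(plate_ids, each = config$wells_per_plate)
  pos_of <- sprintf("w%03d", rep(seq_len(config$wells_per_plate),
                                 config$n_plates))

  t <- config$ts * (0:(config$n - 1))
  base <- unlist(config$base_params)[pars]
  wsd <- unlist(config$well_sd)[pars]
  arr <- runif(n_wells) < ifelse(is.na(well_gene), 0, config$arrhythmic_fraction)

  par_mat <- matrix(rep(base, each = n_wells), n_wells, 4,
                    dimnames = list(NULL, pars))
  for (p in pars) par_mat[, p] <- par_mat[, p] + rnorm(n_wells, 0, wsd[p])
  has_gene <- !is.na(well_gene)
  par_mat[has_gene, ] <- par_mat[has_gene, ] + shift[well_gene[has_gene], ]
  par_mat <- par_mat + plate_eff[plate_of, ]
  par_mat[, "period"] <- pmax(8, par_mat[, "period"])

  mat <- matrix(0, n_wells, config$n)
  for (i in seq_len(n_wells)) {
    if (arr[i]) {
      e <- rnorm(config$n, sd = 0.3)
      ar1 <- as.numeric(stats::filter(e, 0.8, method = "recursive"))
      mat[i, ] <- ar1 + 0.5 * sin(2 * pi * t / 200 + runif(1, 0, 2 * pi))
    } else {
      mat[i, ] <- exp(par_mat[i, "ln_amplitude"]) *
        exp(-par_mat[i, "damping"] * t) *
        sin(2 * pi * t / par_mat[i, "period"] + par_mat[i, "phase"])
    }
  }
  mat <- mat + rnorm(length(mat), sd = config$noise_sd)

  colnames(mat) <- sprintf("t%d", 0:(config$n - 1))
  out <- dplyr::bind_cols(
    tibble::tibble(plate_id = plate_of, well_pos = pos_of,
                   gene_id = well_gene,
                   category = ifelse(is.na(well_gene), "control", "perturbed")),
    tibble::as_tibble(mat)
  )
  attr(out, "truth") <- list(params = tibble::as_tibble(par_mat) |>
                               dplyr::mutate(arrhythmic = arr),
                             gene_shifts = shift, plate_effects = plate_eff,
                             robust_genes = if (config$robust_quadrant_fraction > 0)
                               gene_ids[seq_len(round(n_genes * config$robust_quadrant_fraction))]
                             else character())
  attr(out, "times") <- t
  attr(out, "config") <- config
  out
}
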