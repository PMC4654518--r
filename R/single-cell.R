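#' Per-cell noise metrics
#'
#' Quantifies the stochastic noise of each single-cell trace by three
#' statistics: the coefficient of variation of cycle periods and of cycle
#' amplitudes (both from the Hilbert-transform cycle statistics of the
#' circadian 8-256 h wavelet band), and a high-frequency noise ratio, the
#' standard deviation of the 1-8 h wavelet band divided by the mean cycle
#' amplitude of the rhythm.
#'
#' @param data Long data frame with columns `cell_id`, `time`, `value`
#'   (raw traces), or a single trace with `time` and `value`.
#' @param circadian_band,hf_band Period bands in hours for the rhythm and the
#'   high-frequency component.
#' @return A tibble with one row per cell: `cell_id`, `cv_period`,
#'   `cv_amplitude`, `hf_noise_ratio`, `n_cycles`.
#' @export
noise_metrics <- function(data, circadian_band = c(8, 256), hf_band = c(1, 8)) {
  if (!"cell_id" %in% names(data)) {
    data <- dplyr::mutate(data, cell_id = "cell")
  }
  dplyr::group_by(data, .data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      rhythm <- wavelet_band_filter(df, band = circadian_band)
      cs <- cycle_statistics(rhythm)
      hf <- wavelet_band_filter(df, band = hf_band)
      tibble::tibble(
        cv_period = sd(cs$periods) / mean(cs$periods),
        cv_amplitude = sd(cs$amplitudes) / mean(cs$amplitudes),
        hf_noise_ratio = sd(hf$value) / mean(cs$amplitudes),
        n_cycles = length(cs$periods)
      )
    }) |>
    dplyr::ungroup()
}

#' Combined noise score by principal components
#'
#' Standardizes the three per-cell noise metrics across cells and projects
#' them onto their first principal component. The sign is oriented so that a
#' larger score means a noisier cell (positive loading on the high-frequency
#' noise ratio).
#'
#' @param metrics A data frame as returned by [noise_metrics()] (>= 3 cells).
#' @return The input tibble with columns `score` (first principal component)
#'   and, as attributes, `loadings` and `prop_var` (variance fraction
#'   explained by the first component).
#' @export
combined_noise_score <- function(metrics) {
  cols <- c("cv_period", "cv_amplitude", "hf_noise_ratio")
  if (nrow(metrics) < 3) abort("need at least 3 cells for a combined score.")
  m <- as.matrix(metrics[cols])
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance metric column: %s",
                  paste(cols[sds == 0], collapse = ", ")))
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  flip <- if (load1["hf_noise_ratio"] < 0) -1 else 1
  out <- dplyr::mutate(metrics, score = flip * pc$x[, 1])
  attr(out, "loadings") <- flip * load1
  attr(out, "prop_var") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' Split cells into low- and high-noise groups
#'
#' Labels the `n_per_group` lowest-scoring cells `"low"` and the
#' `n_per_group` highest `"high"`; any cells in between stay unlabeled
#' (`NA`). Ties are broken by cell id (stable sort), so the assignment is
#' deterministic.
#'
#' @param scores Data frame with `cell_id` and `score` columns (e.g. from
#'   [combined_noise_score()]).
#' @param n_per_group Cells per tail; at most `floor(n / 2)`.
#' @return The input with a `noise_group` column (`"low"`, `"high"`, or
#'   `NA`).
#' @export
split_noise_groups <- function(scores, n_per_group) {
  n <- nrow(scores)
  if (n_per_group > floor(n / 2)) {
    abort("`n_per_group` must not exceed half the number of cells.")
  }
  ord <- order(scores$score, scores$cell_id)
  grp <- rep(NA_character_, n)
  grp[ord[seq_len(n_per_group)]] <- "low"
  grp[ord[seq(n - n_per_group + 1, n)]] <- "high"
  dplyr::mutate(scores, noise_group = grp)
}

#' Synchronize traces in silico and average them
#'
#' Raw single-cell recordings are not synchronized, so the population-level
#' desynchronization experiment is emulated by shifting each trace to start
#' at its first upward phase zero-crossing (Hilbert transform of the
#' band-filtered trace) and averaging pointwise up to the shortest truncated
#' length.
#'
#' @param data Long data frame with `cell_id`, `time`, `value`.
#' @param band Wavelet period band (hours) used to denoise before phase
#'   estimation and averaging.
#' @return A tibble with `time` (starting at 0) and `value` (mean across
#'   cells). Cells with no detectable crossing are dropped with a warning.
#' @export
align_and_average <- function(data, band = c(8, 256)) {
  pieces <- aligned_pieces(data, band)
  average_pieces(pieces, attr(pieces, "ts"))
}

# Band-filter, truncate at first upward phase zero-crossing. Returns a list
# of numeric vectors (one per cell); used by the bootstrap so the expensive
# per-cell work happens once.
aligned_pieces <- function(data, band = c(8, 256)) {
  stopifnot("cell_id" %in% names(data))
  ts <- series_interval(data[data$cell_id == data$cell_id[1], ])
  split_df <- split(data, data$cell_id)
  pieces <- list()
  dropped <- character()
  for (nm in names(split_df)) {
    df <- split_df[[nm]]
    bf <- wavelet_band_filter(df, band = band)
    z <- analytic_signal_ext(bf$value, ts)
    ph <- Arg(z)
    n <- length(ph)
    up <- which(ph[-n] < 0 & ph[-1] >= 0 & (ph[-1] - ph[-n]) < pi)
    if (length(up) == 0) {
      dropped <- c(dropped, nm)
      next
    }
    pieces[[nm]] <- bf$value[(up[1] + 1):n]
  }
  if (length(dropped) > 0) {
    warn(sprintf("no phase zero-crossing found for %d cell(s): %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(pieces) == 0) abort("no cells with a detectable phase crossing.")
  attr(pieces, "ts") <- ts
  pieces
}

average_pieces <- function(pieces, ts) {
  len <- min(lengths(pieces))
  m <- vapply(pieces, function(p) p[seq_len(len)], numeric(len))
  tibble::tibble(time = ts * (seq_len(len) - 1), value = rowMeans(m))
}

#' Bootstrap test for a damping-rate difference between noise groups
#'
#' The observed statistic is `|d_high - d_low|`, the absolute difference in
#' damping rate between the aligned-and-averaged high- and low-noise
#' populations, each fit with a damped sinusoid over the first
#' `window_hours` hours. The null distribution is built by randomly
#' reassigning cells evenly to two groups (one random cell omitted per trial
#' when the pooled count is odd) and recomputing the statistic; the p-value
#' is `(1 + #{trial >= observed}) / (n_trials + 1)` (two-tailed by
#' construction of the absolute difference).
#'
#' @param data Long data frame with `cell_id`, `time`, `value`.
#' @param groups Data frame with `cell_id` and `noise_group` (from
#'   [split_noise_groups()]); only labeled cells enter the test.
#' @param n_trials Number of bootstrap reassignments (>= 100).
#' @param window_hours Fit window from the aligned start (default 96 h: four
#'   days).
#' @param band Wavelet band for denoising/alignment.
#' @param config Fit configuration; refinement is disabled here by default
#'   for speed.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"bootstrap_result"`: list with
#'   `observed_stat`, `p_value`, `n_trials`, `trial_stats`, `d_low`,
#'   `d_high`.
#' @export
bootstrap_damping_difference <- function(data, groups, n_trials = 1000,
                                         window_hours = 96, band = c(8, 256),
                                         config = fit_config(refine = FALSE),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_trials < 100) abort("`n_trials` must be at least 100.")
  keep <- groups$cell_id[!is.na(groups$noise_group)]
  lab <- setNames(groups$noise_group[!is.na(groups$noise_group)],
                  groups$cell_id[!is.na(groups$noise_group)])
  data <- data[data$cell_id %in% keep, ]
  pieces <- aligned_pieces(data, band)
  ts <- attr(pieces, "ts")
  nwin <- max(8L, round(window_hours / ts))

  len <- min(min(lengths(pieces)), nwin)
  mat <- vapply(pieces, function(p) p[seq_len(len)], numeric(len))
  fit_d <- function(ids) {
    v <- rowMeans(mat[, ids, drop = FALSE])
    if (config$refine) {
      fit_damped_sinusoid(tibble::tibble(time = ts * (seq_len(len) - 1),
                                         value = v), config)$damping
    } else {
      unname(fit_damping_core(v, ts, config)["damping"])
    }
  }

  ids <- names(pieces)
  d_low <- fit_d(ids[lab[ids] == "low"])
  d_high <- fit_d(ids[lab[ids] == "high"])
  observed <- abs(d_high - d_low)

  n_all <- length(ids)
  half <- floor(n_all / 2)
  stats_out <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    for (attempt in 1:10) {
      perm <- sample(ids, 2 * half)  # odd count: one cell randomly omitted
      s <- tryCatch(
        abs(fit_d(perm[seq_len(half)]) - fit_d(perm[half + seq_len(half)])),
        error = function(e) NA_real_
      )
      if (is.finite(s)) break
    }
    if (!is.finite(s)) abort("bootstrap trial failed repeatedly.")
    stats_out[k] <- s
  }
  structure(
    list(
      observed_stat = observed, d_low = d_low, d_high = d_high,
      p_value = (1 + sum(stats_out >= observed)) / (n_trials + 1),
      n_trials = n_trials, trial_stats = stats_out
    ),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Bootstrap damping-rate difference test\n")
  cat(sprintf("  d_low = %.4g, d_high = %.4g (1/h)\n", x$d_low, x$d_high))
  cat(sprintf("  |d_high - d_low| = %.4g, p = %.4g (%d trials)\n",
              x$observed_stat, x$p_value, x$n_trials))
  invisible(x)
}

#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble::tibble(
    observed_stat = x$observed_stat, d_low = x$d_low, d_high = x$d_high,
    p.value = x$p_value, n_trials = x$n_trials
  )
}

#' Within- versus between-cell period variability
#'
#' For each cell, collects the cycle-to-cycle period distribution (from the
#' band-filtered Hilbert cycle statistics) and summarizes its interquartile
#' range; the across-cell IQR is the IQR of per-cell mean periods. The
#' fraction of cells whose within-cell IQR exceeds the across-cell IQR
#' quantifies whether cycle-to-cycle variability dominates cell-to-cell
#' heterogeneity.
#'
#' @param data Long data frame with `cell_id`, `time`, `value`.
#' @param band Wavelet period band (hours).
#' @param min_cycles Minimum detected cycles per cell (cells below are
#'   dropped).
#' @return A list with `per_cell` (tibble: `cell_id`, `mean_period`,
#'   `within_iqr`, `n_cycles`), `across_iqr`, `mean_within_iqr`, and
#'   `frac_within_exceeds`.
#' @export
period_variability_decomposition <- function(data, band = c(8, 256),
                                             min_cycles = 3) {
  stopifnot("cell_id" %in% names(data))
  per_cell <- dplyr::group_by(data, .data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      cs <- tryCatch(cycle_statistics(wavelet_band_filter(df, band = band)),
                     error = function(e) NULL)
      if (is.null(cs) || length(cs$periods) < min_cycles) {
        return(tibble::tibble(mean_period = NA_real_, within_iqr = NA_real_,
                              n_cycles = if (is.null(cs)) 0L else length(cs$periods)))
      }
      tibble::tibble(mean_period = mean(cs$periods),
                     within_iqr = IQR(cs$periods),
                     n_cycles = length(cs$periods))
    }) |>
    dplyr::ungroup()
  ok <- per_cell[!is.na(per_cell$within_iqr), ]
  if (nrow(ok) < 2) abort("fewer than 2 cells with enough detected cycles.")
  across <- IQR(ok$mean_period)
  list(
    per_cell = ok,
    across_iqr = across,
    mean_within_iqr = mean(ok$within_iqr),
    frac_within_exceeds = mean(ok$within_iqr > across)
  )
}
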