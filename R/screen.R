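#' Batch-fit a plate-format screen with quality control
#'
#' Fits a damped sinusoid to every well of a wide plate table and applies
#' the R-squared quality filter: wells whose fit has `r_squared < r2_min`
#' fail QC (their sinusoidal parameters cannot be confidently inferred:
#' arrhythmic, toxic or dead wells). The natural logarithm of the fitted
#' amplitude is stored alongside, since it is closer to normally distributed
#' and on a scale comparable to the damping rate.
#'
#' @param wells Wide data frame: metadata columns (`plate_id`, `well_pos`,
#'   optionally `gene_id`, `category`) followed by time-point columns
#'   `t0 ... t{N-1}` (or any all-numeric trailing columns).
#' @param ts Sampling interval in hours (screen data are typically 2 h).
#' @param r2_min QC threshold on the fit R-squared (default 0.80).
#' @param config Fit configuration; defaults to the fast (no refinement)
#'   pipeline.
#' @return A tibble of well records: metadata, fitted `amplitude`,
#'   `ln_amplitude`, `damping`, `period`, `phase`, `r_squared`, `qc_pass`.
#'   Wells with non-finite data or failed fits are dropped; stage counts are
#'   attached as attribute `"counts"` (`n_raw`, `n_fit`, `n_qc`).
#' @export
batch_fit_and_qc <- function(wells, ts = 2, r2_min = 0.80,
                             config = fit_config(refine = FALSE)) {
  meta_cols <- intersect(c("plate_id", "well_pos", "gene_id", "category"),
                         names(wells))
  tcols <- setdiff(names(wells), meta_cols)
  mat <- as.matrix(wells[tcols])
  if (!is.numeric(mat)) abort("time-point columns must be numeric.")
  if (!"category" %in% meta_cols) {
    wells$category <- if ("gene_id" %in% meta_cols) {
      ifelse(is.na(wells$gene_id) | wells$gene_id == "", "control", "perturbed")
    } else "control"
    meta_cols <- c(meta_cols, "category")
  }
  t <- ts * (seq_len(ncol(mat)) - 1)
  n_raw <- nrow(mat)
  rows <- vector("list", n_raw)
  for (i in seq_len(n_raw)) {
    y <- mat[i, ]
    if (!all(is.finite(y))) next
    f <- tryCatch(
      fit_damped_sinusoid(tibble::tibble(time = t, value = y), config),
      error = function(e) NULL
    )
    if (is.null(f)) next
    rows[[i]] <- tibble::tibble(
      amplitude = f$amplitude, ln_amplitude = log(f$amplitude),
      damping = f$damping, period = f$period,
      phase = wrap_phase(f$phase), r_squared = f$r_squared
    )
  }
  fitted_idx <- which(!vapply(rows, is.null, logical(1)))
  out <- dplyr::bind_cols(
    wells[fitted_idx, meta_cols],
    dplyr::bind_rows(rows[fitted_idx])
  )
  out$qc_pass <- out$r_squared >= r2_min
  attr(out, "counts") <- c(n_raw = n_raw, n_fit = nrow(out),
                           n_qc = sum(out$qc_pass))
  out
}

#' Robust per-plate z-score normalization
#'
#' Normalizes each fitted parameter on a plate-by-plate basis with a robust
#' z-score, `z = (p - median(p)) / median(|p - median(p)|)`, computed over
#' the QC-passing wells of the plate. The median absolute deviation is used
#' raw (no consistency constant), so `[1, 2, 3]` maps to `[-1, 0, 1]`.
#'
#' @param records Well records from [batch_fit_and_qc()].
#' @param params Parameters to normalize (default `period`,
#'   `ln_amplitude`, `damping`, `phase`).
#' @param min_wells Minimum QC-passing wells a plate needs (default 5).
#' @return The records with added `z_<param>` columns (QC-failing wells get
#'   `NA`). Plates with a zero median absolute deviation in some parameter
#'   have that column set to `NA` with a warning.
#' @export
plate_normalize <- function(records,
                            params = c("period", "ln_amplitude",
                                       "damping", "phase"),
                            min_wells = 5) {
  stopifnot(all(params %in% names(records)))
  out <- records
  for (p in params) out[[paste0("z_", p)]] <- NA_real_
  for (pl in unique(records$plate_id)) {
    sel <- records$plate_id == pl & records$qc_pass
    if (sum(sel) < min_wells) {
      warn(sprintf("plate %s has fewer than %d QC-passing wells; left unnormalized.",
                   pl, min_wells))
      next
    }
    for (p in params) {
      v <- records[[p]][sel]
      med <- median(v)
      mad_raw <- median(abs(v - med))
      if (mad_raw == 0) {
        warn(sprintf("plate %s: zero median absolute deviation for %s.", pl, p))
        next
      }
      out[[paste0("z_", p)]][sel] <- (v - med) / mad_raw
    }
  }
  out
}

#' Moments and correlations of the normalized screen parameters
#'
#' Flags outliers (any robust z-score with absolute value above `z_max`),
#' removes them, and reports per-category moments (mean, variance,
#' skewness, excess kurtosis) of each normalized parameter plus the Pearson
#' correlation matrix across parameters.
#'
#' @param records Normalized records from [plate_normalize()].
#' @param z_max Outlier threshold on any |z| (default 8).
#' @param params Parameters (z-columns are `z_<param>`).
#' @return A list with `records` (input plus `outlier` flag), `moments` (a
#'   tibble: category x parameter moments), `correlations` (matrix over the
#'   z-scores of all retained wells), and `counts` (wells at each filter
#'   stage).
#' @export
summarize_distributions <- function(records, z_max = 8,
                                    params = c("period", "ln_amplitude",
                                               "damping", "phase")) {
  zc <- paste0("z_", params)
  stopifnot(all(zc %in% names(records)))
  zm <- as.matrix(records[zc])
  has_z <- stats::complete.cases(zm)
  records$outlier <- has_z & (apply(abs(zm), 1, max) > z_max)
  keep <- has_z & !records$outlier
  kept <- records[keep, ]

  skewness <- function(v) mean((v - mean(v))^3) / sd(v)^3
  ex_kurtosis <- function(v) mean((v - mean(v))^4) / var(v)^2 - 3
  moments <- tidyr::expand_grid(category = unique(kept$category),
                                parameter = params) |>
    purrr::pmap(function(category, parameter) {
      v <- kept[[paste0("z_", parameter)]][kept$category == category]
      tibble::tibble(category = category, parameter = parameter,
                     n = length(v), mean = mean(v), variance = var(v),
                     skewness = skewness(v), ex_kurtosis = ex_kurtosis(v))
    }) |>
    dplyr::bind_rows()

  cors <- stats::cor(as.matrix(kept[zc]))
  dimnames(cors) <- list(params, params)
  list(
    records = records,
    moments = moments,
    correlations = cors,
    counts = c(n_normalized = sum(has_z), n_outlier = sum(records$outlier),
               n_kept = sum(keep))
  )
}

#' Regression of damping rate on the other fitted parameters
#'
#' Ordinary least squares of the normalized damping rate on normalized
#' period, log-amplitude, phase, and the perturbation-type indicator
#' (0 = control, 1 = perturbed), quantifying how much of the variation in
#' damping is explained by the other oscillation parameters. A low
#' R-squared indicates that damping (and hence stochastic noise) is an
#' independently perturbed feature.
#'
#' @param records Normalized records (outliers should be flagged via
#'   [summarize_distributions()]; rows with `outlier == TRUE` are dropped).
#' @return A list with `fit` (the `lm` object), `coefficients` (tidy
#'   tibble), and `r_squared`. A condition-number warning is raised for
#'   near-collinear designs.
#' @export
regress_damping <- function(records) {
  df <- records
  if ("outlier" %in% names(df)) df <- df[!df$outlier, ]
  df <- df[stats::complete.cases(df[c("z_damping", "z_period",
                                      "z_ln_amplitude", "z_phase")]), ]
  df$perturbed <- as.integer(df$category == "perturbed")
  fit <- lm(z_damping ~ z_period + z_ln_amplitude + z_phase + perturbed,
            data = df)
  x <- stats::model.matrix(fit)
  kappa_x <- kappa(x, exact = FALSE)
  if (kappa_x > 1e6) warn(sprintf("design matrix is near-collinear (condition number %.3g).", kappa_x))
  sm <- summary(fit)
  list(
    fit = fit,
    coefficients = tibble::tibble(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, 1],
      std_error = sm$coefficients[, 2],
      statistic = sm$coefficients[, 3],
      p_value = sm$coefficients[, 4]
    ),
    r_squared = sm$r.squared,
    n = nrow(df)
  )
}

#' Per-gene Hotelling T-squared test against the control distribution
#'
#' Groups perturbed wells by gene, and tests whether each gene's mean
#' z-score vector differs from the control population. The control location
#' and scatter are estimated with a robust (minimum covariance determinant)
#' estimator; because the control population is far larger than any gene
#' group, the gene sample's effect on the pooled covariance is neglected:
#' `T2 = n * (xbar - mu0)' S0^-1 (xbar - mu0)`, with p-values from the
#' chi-squared approximation with as many degrees of freedom as parameters.
#'
#' @param records Normalized records (outliers removed or flagged).
#' @param params Parameters entering the test (default all four z-scores).
#' @param alpha Significance level (default 0.01).
#' @param quantile_used Support fraction for the robust covariance
#'   estimator (passed to [MASS::cov.rob()] as `quantile.used`; default
#'   ~90% of control wells).
#' @return A tibble with one row per gene: `gene_id`, `n`, `t2`, `p_value`,
#'   `significant`, and the mean shift `shift_<param>` relative to the
#'   robust control center. Control center and covariance are attached as
#'   attributes `"center"` and `"cov"`. Genes with `n = 1` are tested but
#'   flagged via the `n` column.
#' @export
gene_group_test <- function(records,
                            params = c("period", "ln_amplitude",
                                       "damping", "phase"),
                            alpha = 0.01, quantile_used = NULL) {
  zc <- paste0("z_", params)
  df <- records
  if ("outlier" %in% names(df)) df <- df[!df$outlier, ]
  df <- df[stats::complete.cases(df[zc]), ]
  ctrl <- as.matrix(df[df$category == "control", zc])
  if (nrow(ctrl) < 10 * length(params)) {
    abort("too few control wells for a robust covariance estimate.")
  }
  qu <- quantile_used %||% floor(0.9 * nrow(ctrl))
  rob <- MASS::cov.rob(ctrl, method = "mcd", quantile.used = qu)
  s_inv <- solve(rob$cov)
  mu <- rob$center

  pert <- df[df$category == "perturbed" & !is.na(df$gene_id), ]
  k <- length(params)
  out <- dplyr::group_by(pert, .data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      xb <- colMeans(as.matrix(g[zc]))
      dv <- xb - mu
      t2 <- nrow(g) * drop(t(dv) %*% s_inv %*% dv)
      shifts <- as.list(setNames(dv, paste0("shift_", params)))
      dplyr::bind_cols(
        tibble::tibble(n = nrow(g), t2 = t2,
                       p_value = pchisq(t2, df = k, lower.tail = FALSE)),
        tibble::as_tibble(shifts)
      )
    }) |>
    dplyr::ungroup()
  out$significant <- out$p_value < alpha
  attr(out, "center") <- mu
  attr(out, "cov") <- rob$cov
  attr(out, "alpha") <- alpha
  out
}

#' Quadrant fractions and radial histogram of significant gene shifts
#'
#' Assigns each significant gene perturbation to a quadrant of the
#' (delta ln-amplitude, delta damping) plane relative to the control center
#' and reports the fraction in each quadrant, plus a radial histogram of
#' shift directions. The quadrant of interest for clock robustness is
#' higher amplitude with lower damping (`higher_A_lower_d`). Shifts exactly
#' on an axis count as nonnegative (`>= 0` is "higher").
#'
#' @param gene_results Output of [gene_group_test()] (uses rows with
#'   `significant == TRUE` unless `only_significant = FALSE`).
#' @param n_bins Number of angular bins for the radial histogram.
#' @param only_significant Restrict to significant genes (default TRUE).
#' @return A list with `fractions` (tibble: quadrant, n, fraction; fractions
#'   sum to 1), `histogram` (tibble: bin midpoints in radians, counts), and
#'   `n_genes`.
#' @export
quadrant_fractions <- function(gene_results, n_bins = 16,
                               only_significant = TRUE) {
  g <- gene_results
  if (only_significant) g <- g[g$significant, ]
  if (nrow(g) == 0) abort("no significant gene shifts to summarize.")
  da <- g$shift_ln_amplitude
  dd <- g$shift_damping
  quad <- dplyr::case_when(
    da >= 0 & dd >= 0 ~ "higher_A_higher_d",
    da < 0 & dd >= 0 ~ "lower_A_higher_d",
    da < 0 & dd < 0 ~ "lower_A_lower_d",
    TRUE ~ "higher_A_lower_d"
  )
  lev <- c("higher_A_higher_d", "lower_A_higher_d",
           "lower_A_lower_d", "higher_A_lower_d")
  tab <- table(factor(quad, levels = lev))
  ang <- atan2(dd, da)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  hist_counts <- table(cut(ang, breaks, include.lowest = TRUE))
  list(
    fractions = tibble::tibble(
      quadrant = lev, n = as.integer(tab),
      fraction = as.numeric(tab) / nrow(g)
    ),
    histogram = tibble::tibble(
      angle_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
      n = as.integer(hist_counts),
      fraction = as.integer(hist_counts) / nrow(g)
    ),
    n_genes = nrow(g)
  )
}

#' Plot the radial histogram of significant gene shifts
#'
#' @param quadrants Output of [quadrant_fractions()].
#' @return A ggplot rose diagram of shift directions in the
#'   (delta ln A, delta d) plane.
#' @export
plot_radial_histogram <- function(quadrants) {
  h <- quadrants$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$angle_mid, y = sqrt(.data$fraction))) +
    ggplot2::geom_col(width = 2 * pi / nrow(h), fill = "#2166ac",
                      colour = "white") +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-pi, pi),
                                breaks = c(-pi / 2, 0, pi / 2, pi),
                                labels = c("lower d", "higher ln A",
                                           "higher d", "lower ln A")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Direction of significant gene perturbations") +
    ggplot2::theme_minimal()
}
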