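#' Hodrick-Prescott detrending
#'
#' Removes a smooth trend `tau` found by penalized least squares, minimizing
#' `sum((x - tau)^2) + gamma * sum(diff(tau, differences = 2)^2)`. With
#' `gamma = "auto"` the smoothing parameter is tied to the sampling interval
#' as `0.05 * (24 / ts)^4`, which keeps the trend slower than circadian
#' frequencies regardless of sampling rate.
#'
#' To suppress end effects, the series is extended on both sides by
#' autoregressive (linear-predictive) extrapolation before the trend is
#' computed, and the extension discarded afterwards (see Details).
#'
#' @param data Data frame with `time` (hours) and `value` columns on a uniform
#'   grid of at least 4 points.
#' @param gamma Smoothing parameter (>= 0), or `"auto"`.
#' @param pad Number of samples of predictive extension on each side, or
#'   `NULL` for the default `ceiling(20 * gamma^0.25)` (the trend's edge
#'   transients decay on a scale of `gamma^0.25` samples).
#'
#' @return A tibble with columns `time`, `value` (the detrended signal) and
#'   `trend`.
#' @details The trend solves the pentadiagonal normal equations
#'   `(I + gamma * D'D) tau = x` exactly (sparse Cholesky), so affine signals
#'   are reproduced exactly and the detrended output is identically zero for
#'   them, for every `gamma > 0`. Without extension the free boundary makes
#'   the trend lock onto the signal near the record ends; least-squares
#'   autoregressive extension continues oscillatory components smoothly (it
#'   is exact for noiseless damped sinusoids) and falls back to even
#'   reflection if the extrapolation misbehaves.
#' @export
hp_detrend <- function(data, gamma = "auto", pad = NULL) {
  x <- series_value(data)
  check_series_values(x)
  ts <- series_interval(data)
  if (identical(gamma, "auto")) gamma <- hp_auto_gamma(ts)
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma < 0) {
    abort("`gamma` must be a single nonnegative number or \"auto\".")
  }
  trend <- hp_trend_padded(x, gamma, ts, pad)
  tibble::tibble(time = series_time(data), value = x - trend, trend = trend)
}

#' @rdname hp_detrend
#' @param ts Sampling interval in hours.
#' @export
hp_auto_gamma <- function(ts) 0.05 * (24 / ts)^4

hp_trend_padded <- function(x, gamma, ts, pad = NULL) {
  if (gamma == 0) return(x)
  n <- length(x)
  pad <- pad %||% ceiling(20 * gamma^0.25)
  xp <- ar_extend(x, pad, ts)
  hp_trend(xp, gamma)[(pad + 1):(pad + n)]
}

# Cache Cholesky factors keyed by (n, gamma): screens re-solve the same
# system tens of thousands of times.
hp_cache <- new.env(parent = emptyenv())

hp_trend <- function(x, gamma) {
  n <- length(x)
  if (gamma == 0) return(x)
  key <- sprintf("%d_%.10g", n, gamma)
  ch <- hp_cache[[key]]
  if (is.null(ch)) {
    d2 <- Matrix::bandSparse(n - 2, n,
      k = 0:2, diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2))
    )
    a <- Matrix::Diagonal(n) + gamma * Matrix::crossprod(d2)
    ch <- Matrix::Cholesky(a, LDL = FALSE)
    if (length(ls(hp_cache)) > 64) rm(list = ls(hp_cache), envir = hp_cache)
    hp_cache[[key]] <- ch
  }
  as.numeric(Matrix::solve(ch, x))
}

# Least-squares autoregressive extension of a series by `pad` samples on both
# sides. The AR predictor is fit by (pseudoinverse) least squares, so for a
# noiseless sum of damped sinusoids the continuation is exact, including the
# growing envelope of a damped oscillation continued backwards. A side whose
# extension is non-finite or explosive falls back to even reflection.
ar_extend <- function(x, pad, ts, order = 12) {
  n <- length(x)
  pad <- max(1L, as.integer(pad))
  p <- min(order, max(2L, floor(n / 3)))
  rng <- diff(range(x)) + 1e-300
  limit <- 1e6 * (max(abs(x - mean(x))) + rng)

  predict_fwd <- function(v) {
    emb <- sapply(0:p, function(k) v[(p - k + 1):(n - k)])
    sv <- svd(emb[, -1, drop = FALSE])
    pos <- sv$d > max(sv$d, 0) * 1e-10
    if (!any(pos)) return(NULL)
    cf <- as.numeric(sv$v[, pos, drop = FALSE] %*%
                       ((t(sv$u[, pos, drop = FALSE]) %*% emb[, 1]) / sv$d[pos]))
    # homogeneous AR recursion seeded with the last p samples
    as.numeric(stats::filter(numeric(pad), cf, method = "recursive",
                             init = rev(tail(v, p))))
  }

  even_pad <- function(side) {
    k <- min(pad, n - 1)
    block <- if (side == "left") x[(k + 1):2] else x[(n - 1):(n - k)]
    # if pad exceeds n - 1, recycle the reflection
    rep(block, length.out = pad)[seq_len(pad)]
  }

  ok <- function(e) !is.null(e) && all(is.finite(e)) && max(abs(e - mean(x))) < limit
  fwd <- tryCatch(predict_fwd(x), error = function(e) NULL)
  bwd <- tryCatch(predict_fwd(rev(x)), error = function(e) NULL)
  right <- if (ok(fwd)) fwd else even_pad("right")
  left <- if (ok(bwd)) rev(bwd) else even_pad("left")
  c(left, x, right)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Smooths a detrended series with an order-`order` Butterworth filter applied
#' forward and backward (zero phase; the effective magnitude response is the
#' squared one-pass response, `1 / (1 + (w / wc)^(2 * order))`). The cutoff is
#' expressed in cycles per sample, so `cutoff = 0.1` keeps periods longer than
#' ten samples regardless of the sampling interval. Edges are handled by
#' autoregressive predictive extension (falling back to even reflection), as
#' in [hp_detrend()].
#'
#' @param data Data frame with `time` and `value` columns.
#' @param order Filter order (default 5).
#' @param cutoff Cutoff frequency in cycles per sample, in (0, 0.5)
#'   (default 0.1).
#' @param pad Samples of edge extension per side (default
#'   `max(3 * (order + 1), 90)`).
#'
#' @return A tibble with columns `time` and `value` (filtered).
#' @export
lowpass_filter <- function(data, order = 5, cutoff = 0.1, pad = NULL) {
  x <- series_value(data)
  check_series_values(x)
  ts <- series_interval(data)
  tibble::tibble(time = series_time(data),
                 value = lowpass_core(x, ts, order, cutoff, pad))
}

butter_cache <- new.env(parent = emptyenv())

lowpass_core <- function(x, ts, order = 5, cutoff = 0.1, pad = NULL) {
  if (!(is.numeric(cutoff) && length(cutoff) == 1 && cutoff > 0 && cutoff < 0.5)) {
    abort("`cutoff` must lie strictly between 0 and 0.5 (cycles per sample).")
  }
  pad <- pad %||% max(3 * (order + 1), 90)
  n <- length(x)
  xp <- ar_extend(x, pad, ts)
  key <- sprintf("%d_%.8g", order, cutoff)
  bf <- butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, 2 * cutoff, type = "low")  # butter() wants Nyquist units
    butter_cache[[key]] <- bf
  }
  yp <- iir_filter(bf$b, bf$a, xp)
  yp <- rev(iir_filter(bf$b, bf$a, rev(yp)))
  yp[(pad + 1):(pad + n)]
}

# direct-form IIR filtering (zero initial conditions); avoids the
# time-series coercion overhead of signal::filter in tight loops
iir_filter <- function(b, a, x) {
  v <- as.numeric(stats::filter(c(numeric(length(b) - 1), x), b,
                                method = "convolution", sides = 1))
  v <- v[-seq_len(length(b) - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v / a[1], -a[-1] / a[1],
                                  method = "recursive"))
  } else {
    v <- v / a[1]
  }
  v
}
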