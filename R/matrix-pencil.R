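#' Matrix-pencil estimation of damped oscillatory modes
#'
#' Estimates the complex exponential modes of a uniformly sampled signal by
#' the matrix pencil method: a Hankel matrix with pencil parameter `L` is
#' formed from the samples, truncated by SVD to the model order, and the
#' generalized eigenproblem of the shifted right-singular-vector blocks yields
#' the signal poles `z_k`. Each pole maps to a damping rate and period through
#' `z = exp((-d + i * 2 * pi / T) * ts)`. The reported mode is the conjugate
#' pair whose period falls inside `config$period_window` with the largest
#' least-squares energy; ties are broken by proximity to 24 h.
#'
#' The input is expected to be detrended and low-pass filtered already (see
#' [fit_damped_sinusoid()] for the full pipeline).
#'
#' @param data Data frame with `time` and `value` columns.
#' @param config A [fit_config()].
#'
#' @return A list with elements `damping` (1/h), `period` (h), and `modes`, a
#'   tibble of all estimated modes (`damping`, `period`, `energy`,
#'   `in_window`).
#' @export
estimate_decay_modes <- function(data, config = fit_config()) {
  y <- series_value(data)
  check_series_values(y)
  ts <- series_interval(data)
  pencil_core(y, ts, config)
}

pencil_core <- function(y, ts, config = fit_config()) {
  n <- length(y)
  l <- config$pencil_parameter %||% max(2L, floor(n / 3))
  if (l >= n) abort("pencil parameter L must be smaller than the series length.")

  # Hankel matrix Y[i, j] = y[i + j - 1], (n - l) x (l + 1)
  ymat <- matrix(y[outer(seq_len(n - l), seq_len(l + 1), `+`) - 1L],
                 nrow = n - l)
  sv <- svd(ymat)
  if (sv$d[1] <= 0) abort("rank-deficient pencil: signal is identically zero.")
  m <- config$model_order %||%
    min(config$max_order, max(1L, sum(sv$d / sv$d[1] >= config$sv_tol)))
  m <- min(m, l)
  v <- sv$v[, seq_len(m), drop = FALSE]
  v1 <- v[seq_len(l), , drop = FALSE]
  v2 <- v[seq_len(l) + 1L, , drop = FALSE]
  # poles are eigenvalues of pinv(V1) V2 (m x m)
  a <- qr.solve(v1, v2)
  z <- eigen(a, only.values = TRUE)$values

  keep <- Mod(z) > 1e-12
  z <- z[keep]
  if (length(z) == 0) abort("no usable poles found.")
  damping <- -log(Mod(z)) / ts
  omega <- Arg(z) / ts               # rad/h, signed
  period <- ifelse(abs(omega) > 1e-12, 2 * pi / abs(omega), Inf)

  # least-squares residues on the complex exponential basis
  basis <- sapply(seq_along(z), function(k) z[k]^(0:(n - 1)))
  amp <- tryCatch(qr.solve(basis, as.complex(y)), error = function(e) {
    rep(NA_complex_, length(z))
  })
  energy <- Mod(amp)^2 * colSums(Mod(basis)^2)

  modes <- tibble::tibble(
    damping = damping, period = period, frequency_sign = sign(omega),
    energy = energy,
    in_window = is.finite(period) &
      period > config$period_window[1] & period < config$period_window[2]
  )
  # one row per conjugate pair: keep positive-frequency member
  cand <- modes[modes$in_window & modes$frequency_sign > 0, , drop = FALSE]
  if (nrow(cand) == 0) {
    abort(sprintf("no oscillatory mode with period in (%g, %g) h found.",
                  config$period_window[1], config$period_window[2]))
  }
  ord <- order(-cand$energy, abs(cand$period - 24))
  best <- cand[ord[1], ]
  list(damping = best$damping, period = best$period, modes = modes)
}
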