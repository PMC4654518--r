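#' Orthonormal wavelet filters by spectral factorization
#'
#' Computes the scaling (low-pass) filter of the Daubechies family with `n`
#' vanishing moments (filter length `2 * n`) by spectral factorization of the
#' Daubechies half-band polynomial. The `"symlet"` variant selects, among the
#' valid root assignments, the one whose transfer function is closest to
#' linear phase (least asymmetric); `"daubechies"` selects the minimum-phase
#' (extremal) factorization.
#'
#' @param n Number of vanishing moments (2 to 10); `n = 6` gives the 12-tap
#'   symlet used by the single-cell band filter.
#' @param family `"symlet"` or `"daubechies"`.
#' @return Numeric vector of `2 * n` scaling-filter coefficients summing to
#'   `sqrt(2)`.
#' @export
wavelet_filter <- function(n = 6, family = c("symlet", "daubechies")) {
  family <- match.arg(family)
  stopifnot(n >= 2, n <= 10)
  # binomial half-band polynomial P(y) = sum C(n-1+k, k) y^k
  py <- choose(n - 1 + 0:(n - 1), 0:(n - 1))
  yr <- polyroot(py)

  # each root y maps to a z-pair via y = (2 - z - 1/z)/4 :
  # z^2 - (2 - 4y) z + 1 = 0
  zpairs <- lapply(yr, function(y) {
    b <- 2 - 4 * y
    disc <- sqrt(as.complex(b^2 - 4))
    c((b + disc) / 2, (b - disc) / 2)
  })
  # group roots: real y gives a real reciprocal z-pair -> one binary choice;
  # complex-conjugate y pairs give quadruples -> one binary choice keeping
  # conjugate symmetry (real filter)
  used <- rep(FALSE, length(yr))
  groups <- list()
  for (i in seq_along(yr)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(yr[i])) < 1e-9) {
      z <- zpairs[[i]]
      groups[[length(groups) + 1]] <- list(a = z[1], b = z[2])
    } else {
      j <- which(!used & abs(yr - Conj(yr[i])) < 1e-7)[1]
      used[j] <- TRUE
      za <- zpairs[[i]]; zb <- zpairs[[j]]
      inside <- c(za, zb)[Mod(c(za, zb)) < 1]
      outside <- c(za, zb)[Mod(c(za, zb)) >= 1]
      groups[[length(groups) + 1]] <- list(a = inside, b = outside)
    }
  }

  build <- function(pick) {
    roots <- unlist(lapply(seq_along(groups), function(g) {
      if (pick[g]) groups[[g]]$a else groups[[g]]$b
    }))
    co <- 1 + 0i
    for (r in roots) co <- c(co, 0) - c(0, co * r)
    for (k in seq_len(n)) co <- c(co, 0) + c(0, co)  # (1 + z)^n factor
    h <- Re(co)
    h * sqrt(2) / sum(h)
  }

  picks <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(groups))))
  cands <- apply(picks, 1, build, simplify = FALSE)
  if (family == "daubechies") {
    # minimum phase: all roots inside the unit circle
    scores <- vapply(cands, function(h) {
      r <- polyroot(h)
      sum(pmax(Mod(r) - 1, 0))
    }, numeric(1))
  } else {
    # least asymmetric: minimize deviation of phase from linear
    w <- seq(0.01, pi - 0.01, length.out = 64)
    scores <- vapply(cands, function(h) {
      hw <- vapply(w, function(wi) sum(h * exp(-1i * wi * (seq_along(h) - 1))),
                   complex(1))
      tau <- (length(h) - 1) / 2
      ph <- Arg(hw * exp(1i * w * tau))
      max(abs(ph))
    }, numeric(1))
  }
  cands[[which.min(scores)]]
}

# quadrature mirror (wavelet) filter from a scaling filter
qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

# Periodic maximal-overlap DWT (undecimated). Returns a matrix of detail
# coefficients (n x levels) and the final smooth; circular filtering, so any
# series length is admissible.
modwt_forward <- function(x, h, levels) {
  n <- length(x)
  ht <- h / sqrt(2)
  gt <- qmf(h) / sqrt(2)
  v <- x
  w <- matrix(0, n, levels)
  for (j in seq_len(levels)) {
    step <- 2^(j - 1)
    idx0 <- seq_len(n) - 1L
    vj <- numeric(n)
    wj <- numeric(n)
    for (l in seq_along(ht)) {
      src <- v[((idx0 - (l - 1) * step) %% n) + 1L]
      vj <- vj + ht[l] * src
      wj <- wj + gt[l] * src
    }
    w[, j] <- wj
    v <- vj
  }
  list(details = w, smooth = v)
}

modwt_inverse <- function(decomp, h) {
  w <- decomp$details
  n <- nrow(w)
  levels <- ncol(w)
  ht <- h / sqrt(2)
  gt <- qmf(h) / sqrt(2)
  v <- decomp$smooth
  idx0 <- seq_len(n) - 1L
  for (j in rev(seq_len(levels))) {
    step <- 2^(j - 1)
    vn <- numeric(n)
    for (l in seq_along(ht)) {
      shift <- ((idx0 + (l - 1) * step) %% n) + 1L
      vn <- vn + ht[l] * v[shift] + gt[l] * w[shift, j]
    }
    v <- vn
  }
  v
}

#' Wavelet band filter for single-cell traces
#'
#' Decomposes a trace with a periodic maximal-overlap discrete wavelet
#' transform (12-tap symlet by default), zeroes every level outside the
#' requested period band, and reconstructs. Level `j` of the transform
#' carries oscillations with periods roughly `2^j` to `2^(j+1)` samples, so a
#' band in hours maps onto the dyadic levels it covers given the sampling
#' interval; the smooth (and DC) component is always excluded.
#'
#' With the default band of 8-256 h this reproduces the usual
#' detrend-and-denoise step for circadian single-cell recordings: baseline
#' drift slower than ~256 h and noise faster than ~8 h are stripped while
#' circadian-range oscillations pass.
#'
#' @param data Data frame with `time` and `value` (a single trace), or
#'   grouped long data with a `cell_id` column (each trace filtered
#'   independently).
#' @param band Two-element numeric, period band in hours (low, high).
#' @param n_vanishing Vanishing moments of the symlet (default 6: 12 taps).
#'
#' @return Tibble with the same columns, `value` replaced by the
#'   band-filtered signal.
#' @export
wavelet_band_filter <- function(data, band = c(8, 256), n_vanishing = 6) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  if ("cell_id" %in% names(data)) {
    return(dplyr::group_modify(
      dplyr::group_by(data, .data$cell_id),
      ~ wavelet_band_filter(.x, band = band, n_vanishing = n_vanishing)
    ) |> dplyr::ungroup())
  }
  x <- series_value(data)
  check_series_values(x, n_min = 8)
  ts <- series_interval(data)
  jlo <- max(1L, as.integer(round(log2(band[1] / ts))))
  jhi <- as.integer(round(log2(band[2] / ts))) - 1L
  if (jhi < jlo) abort("period band too narrow for the sampling interval.")
  h <- wavelet_filter(n_vanishing, "symlet")
  # boundary handling: extend the trace by linear prediction on both sides
  # (top-level filters span many cycles, so raw circular wrap-around would
  # leak record edges across the whole trace), transform the extended series
  # circularly, keep the interior
  n <- length(x)
  pad <- min((length(h) - 1) * 2^(jhi - 1), 3 * n)
  xe <- ar_extend(x - mean(x), pad, ts)
  dec <- modwt_forward(xe, h, jhi)
  if (jlo > 1) dec$details[, seq_len(jlo - 1)] <- 0
  dec$smooth[] <- 0
  tibble::tibble(time = series_time(data),
                 value = modwt_inverse(dec, h)[pad + seq_len(n)])
}
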