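#' Construct a uniformly sampled bioluminescence series
#'
#' The package represents a single population-level recording as an ordinary
#' tibble with a `time` column (hours) and a `value` column (arbitrary
#' luminescence units). `bl_series()` builds one from a vector of values and a
#' sampling interval; most analysis functions accept any data frame with these
#' two columns and recover the sampling interval from the time grid.
#'
#' @param value Numeric vector of luminescence values (all finite).
#' @param ts Sampling interval in hours (> 0).
#' @param start Time of the first sample in hours (default 0).
#'
#' @return A tibble with columns `time` and `value`.
#' @examples
#' x <- bl_series(sin(2 * pi * (0:95) / 24), ts = 1)
#' @export
bl_series <- function(value, ts, start = 0) {
  value <- as.numeric(value)
  check_series_values(value)
  if (!is.numeric(ts) || length(ts) != 1 || !is.finite(ts) || ts <= 0) {
    abort("`ts` must be a single positive number (hours).")
  }
  tibble::tibble(time = start + ts * (seq_along(value) - 1), value = value)
}

check_series_values <- function(value, n_min = 4) {
  if (length(value) < n_min) {
    abort(sprintf("series must contain at least %d points, got %d.",
                  n_min, length(value)))
  }
  if (!all(is.finite(value))) {
    abort("series values must all be finite.")
  }
  invisible(value)
}

#' Sampling interval of a uniform time grid
#'
#' Infers the sampling interval from the `time` column and errors if the grid
#' is not uniform to within a relative tolerance of 1e-6.
#'
#' @param data Data frame with a numeric `time` column in hours.
#' @return The sampling interval in hours.
#' @export
series_interval <- function(data) {
  t <- series_time(data)
  dt <- diff(t)
  ts <- median(dt)
  if (ts <= 0 || any(abs(dt - ts) > 1e-6 * max(ts, 1))) {
    abort("`time` must form an increasing, uniform grid (tolerance 1e-6).")
  }
  ts
}

series_time <- function(data) {
  if (!all(c("time", "value") %in% names(data))) {
    abort("`data` must contain `time` and `value` columns.")
  }
  as.numeric(data[["time"]])
}

series_value <- function(data) as.numeric(data[["value"]])
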