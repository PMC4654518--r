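# shared constructors for clean test signals

damped_sine <- function(amplitude = 5, damping = 0.02, period = 24,
                        phase = 1, ts = 0.5, n = 192, offset = 0) {
  t <- ts * (0:(n - 1))
  bl_series(amplitude * exp(-damping * t) * sin(2 * pi * t / period + phase) +
              offset, ts = ts)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
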