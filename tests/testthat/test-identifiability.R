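test_that("window functions recover exact envelopes by both methods", {
  t <- 0.5 * (0:479)
  d <- tibble::tibble(time = t, value = exp(-0.02 * t) * sin(2 * pi * t / 24))
  # suppressWarnings: summary.lm() flags the (intended) perfect fit
  for (meth in c("hilbert", "local_peaks")) {
    w <- window_function(d, meth)
    fit <- suppressWarnings(envelope_shape_fit(w))
    expect_lt(abs(fit$damping - 0.02), 0.001)
  }
  # the two methods agree on the slope within 10%
  s1 <- suppressWarnings(envelope_shape_fit(window_function(d, "hilbert")))$damping
  s2 <- suppressWarnings(envelope_shape_fit(window_function(d, "local_peaks")))$damping
  expect_lt(abs(s1 - s2) / s1, 0.1)

  # constant amplitude: slope ~ 0
  d0 <- tibble::tibble(time = t, value = sin(2 * pi * t / 24))
  f0 <- envelope_shape_fit(window_function(d0, "hilbert"))
  expect_lt(abs(f0$damping), 1e-3)
})

test_that("gaussian envelopes are flagged by the curvature test", {
  t <- 0.5 * (0:479)
  dg <- tibble::tibble(time = t,
                       value = exp(-(0.012 * t)^2) * sin(2 * pi * t / 24))
  fg <- envelope_shape_fit(window_function(dg, "hilbert"))
  expect_equal(fg$preferred, "gaussian")
  expect_lt(fg$curvature$estimate, 0)
  # curvature of log A = -(0.012 t)^2 is -0.012^2
  expect_rel_equal(abs(fg$curvature$estimate), 0.012^2, 0.1)

  de <- tibble::tibble(time = t, value = exp(-0.02 * t) * sin(2 * pi * t / 24))
  fe <- envelope_shape_fit(window_function(de, "hilbert"))
  expect_equal(fe$preferred, "exponential")
})

test_that("pure phase-diffusion populations prefer the exponential envelope", {
  set.seed(61)
  D <- 0.01
  ts <- 0.5
  t <- ts * (0:287)
  w <- 2 * pi / 24
  pop <- rowMeans(cos(w * t + outer(sqrt(2 * D * t), rnorm(3000))))
  det <- hp_detrend(bl_series(pop, ts))
  fit <- envelope_shape_fit(window_function(det, "hilbert"))
  expect_equal(fit$preferred, "exponential")
  expect_rel_equal(fit$damping, D, 0.1)
})

test_that("pure period heterogeneity yields a gaussian envelope with known curvature", {
  set.seed(63)
  ts <- 0.5
  t <- ts * (0:287)
  sigma_w <- 0.012                     # SD of angular frequencies
  ws <- 2 * pi / 24 + sigma_w * rnorm(4000)
  pop <- rowMeans(cos(outer(t, ws)))
  det <- hp_detrend(bl_series(pop, ts))
  fit <- envelope_shape_fit(window_function(det, "hilbert"))
  expect_equal(fit$preferred, "gaussian")
  # envelope exp(-sigma_w^2 t^2 / 2): curvature -sigma_w^2 / 2
  expect_rel_equal(abs(fit$curvature$estimate), sigma_w^2 / 2, 0.15)
})

test_that("stochastic mixed populations reproduce the limiting regimes", {
  # extrinsic-only: essentially deterministic cells, heterogeneous periods
  mix <- simulate_mixed_population(
    mixed_noise_config(n_cells = 300, omega = 5000, period_sd = 0.05,
                       duration = 120), seed = 3)
  det <- hp_detrend(mix$mean)
  fit <- envelope_shape_fit(window_function(det, "local_peaks"))
  expect_equal(fit$preferred, "gaussian")

  # intrinsic-only at large volume: nearly undamped mean
  pure <- simulate_mixed_population(
    mixed_noise_config(n_cells = 200, omega = 5000, period_sd = 0,
                       duration = 120), seed = 5)
  fitp <- fit_damped_sinusoid(pure$mean, fit_config(refine = FALSE))
  expect_lt(abs(fitp$damping), 0.004)
})

test_that("per-cell periods are rescaled by the drawn heterogeneity", {
  mix <- simulate_mixed_population(
    mixed_noise_config(n_cells = 3, omega = 3000, period_sd = 0.04,
                       duration = 144), seed = 7)
  for (i in 1:3) {
    cs <- cycle_statistics(tibble::tibble(
      time = mix$mean$time,
      value = mix$cells[, i] - mean(mix$cells[, i])
    ))
    expect_lt(abs(mean(cs$periods) - mix$periods[i]) / mix$periods[i], 0.05)
  }
})
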