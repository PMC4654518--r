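test_that("the toy oscillator has a robust deterministic limit cycle", {
  m <- toy_oscillator_model(period_hours = 24)
  lc <- limit_cycle(m, t_transient = 800, t_end = 1600)
  expect_lt(abs(lc$period - 24), 0.1)
  # period is an attractor property: two different initial conditions agree
  lc2 <- limit_cycle(m, t_transient = 800, t_end = 1600)
  tr <- simulate_deterministic(m, t_end = 1600, dt_out = 0.1,
                               x0 = c(M = 2, Pc = 0.05, PN = 0.3))
  late <- tr[tr$time > 800, ]
  pk <- which(diff(sign(diff(late$M))) == -2) + 1
  expect_lt(abs(mean(diff(late$time[pk])) - lc$period) / lc$period, 0.01)
  # sustained: consecutive late peaks equal within 1%
  vp <- late$M[pk]
  expect_lt(abs(vp[length(vp)] - vp[length(vp) - 1]) / diff(range(late$M)),
            0.01)
})

test_that("silencing transcription collapses every species to zero", {
  m <- toy_oscillator_model(params = c(v1 = 1e-9))
  tr <- simulate_deterministic(m, t_end = 400, dt_out = 1,
                               x0 = c(M = 1, Pc = 1, PN = 1))
  expect_true(all(tail(as.matrix(tr[, -1]), 1) < 1e-3))
  # trajectories decay monotonically after an initial transient
  expect_true(all(diff(tr$M[-(1:5)]) <= 1e-9))
})

test_that("the stochastic mean approaches the deterministic solution at large volume", {
  m <- toy_oscillator_model(period_hours = 24)
  x0 <- limit_cycle(m)$state
  det <- simulate_deterministic(m, t_end = 72, dt_out = 0.5, x0 = x0)
  rel_rms <- function(omega, n_cells, seed) {
    pop <- simulate_population(m, omega = omega, n_cells = n_cells,
                               t_end = 72, dt_out = 0.5, x0 = x0,
                               seed = seed, method = "exact")
    sqrt(mean((pop$mean$M - det$M)^2)) / sd(det$M)
  }
  e_hi <- rel_rms(5000, 100, seed = 1)
  expect_lt(e_hi, 0.05)
  # noise scaling: 4x volume roughly halves the deviation
  e_lo <- rel_rms(100, 100, seed = 2)
  e_mid <- rel_rms(400, 100, seed = 3)
  expect_gt(e_lo / e_mid, 1.4)
})

test_that("identical seeds reproduce trajectories; different seeds decorrelate cells", {
  m <- toy_oscillator_model()
  x0 <- limit_cycle(m)$state
  a <- simulate_population(m, omega = 50, n_cells = 5, t_end = 144,
                           seed = 11, track = "M")
  b <- simulate_population(m, omega = 50, n_cells = 5, t_end = 144,
                           seed = 11, track = "M")
  expect_identical(a$mean, b$mean)
  expect_identical(a$cells, b$cells)
  # cells desynchronize: late-window pairwise correlations fall well below 1
  late <- a$cells[a$mean$time > 96, ]
  cc <- cor(late)
  off <- cc[upper.tri(cc)]
  expect_lt(mean(abs(off)), 0.9)
  expect_gt(sd(as.numeric(a$cells[, 1] - a$cells[, 2])), 0)
})

test_that("species counts stay nonnegative integers in both simulators", {
  m <- toy_oscillator_model()
  x0 <- limit_cycle(m)$state
  for (meth in c("exact", "tau")) {
    pop <- simulate_population(m, omega = 30, n_cells = 3, t_end = 48,
                               method = meth, seed = 5, track = "M")
    counts <- pop$cells
    expect_true(all(counts >= 0))
    expect_true(all(abs(counts - round(counts)) < 1e-9))
  }
})

test_that("tau-leaping matches the exact SSA distributionally", {
  m <- toy_oscillator_model(period_hours = 24)
  x0 <- limit_cycle(m)$state
  cycle_cv <- function(method) {
    pop <- simulate_population(m, omega = 150, n_cells = 24, t_end = 240,
                               dt_out = 0.5, method = method, tau = 0.05,
                               x0 = x0, seed = 21, track = "M")
    cvs <- apply(pop$cells, 2, function(v) {
      cs <- cycle_statistics(tibble::tibble(time = pop$mean$time,
                                            value = v - mean(v)))
      sd(cs$periods) / mean(cs$periods)
    })
    mean(cvs)
  }
  cv_exact <- cycle_cv("exact")
  cv_tau <- cycle_cv("tau")
  expect_lt(abs(cv_tau - cv_exact) / cv_exact, 0.3)
  expect_gt(cv_exact, 0)
})

test_that("population damping decreases with volume and the fit accepts clean runs", {
  m <- toy_oscillator_model(period_hours = 24)
  x0 <- limit_cycle(m)$state
  set.seed(31)
  ds <- vapply(c(50, 200, 800), function(om) {
    pop <- simulate_population(m, omega = om, n_cells = 150, t_end = 120,
                               x0 = x0, tau = 0.05)
    fit_population_damping(pop)$damping
  }, numeric(1))
  expect_true(all(diff(ds) < 0))

  # deterministic limit: damping ~ 0, pooled R2 ~ 1
  det <- simulate_deterministic(m, t_end = 120, dt_out = 0.5, x0 = x0)
  fake_pop <- structure(list(mean = det, omega = Inf, n_cells = 1,
                             model = m, dt_out = 0.5),
                        class = "population_result")
  ft <- fit_population_damping(fake_pop)
  # waveform harmonics of the relaxation oscillator cap the sinusoid fit
  expect_gt(ft$pooled_r2, 0.95)
  expect_true(ft$accepted)
  expect_lt(abs(ft$damping), 1e-3)
})

test_that("a phase-diffusing analytic population is fit at its known damping", {
  # cells cos(w t + sqrt(2 D t) Z): population envelope exp(-D t)
  set.seed(41)
  D <- 0.01
  ts <- 0.5
  t <- ts * (0:239)
  n_cells <- 4000
  w <- 2 * pi / 24
  phases <- outer(sqrt(2 * D * t), rnorm(n_cells))
  pop_mean <- rowMeans(cos(w * t + phases))
  f <- fit_damped_sinusoid(bl_series(pop_mean + 1, ts))
  expect_rel_equal(f$damping, D, 0.1)
})

test_that("noise-dominated populations are rejected by the pooled R2 rule", {
  m <- toy_oscillator_model(period_hours = 24)
  x0 <- limit_cycle(m)$state
  pop <- simulate_population(m, omega = 1.5, n_cells = 3, t_end = 120,
                             x0 = x0, seed = 51, tau = 0.02)
  ft <- tryCatch(fit_population_damping(pop), error = function(e) NULL)
  expect_true(is.null(ft) || !ft$accepted)
})
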