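make_noisy_cell <- function(id, sigma_hf = 0, sigma_cycle = 0, seed = 1,
                            duration = 240, ts = 0.5, period = 24) {
  set.seed(seed)
  t <- seq(0, duration, by = ts)
  n_cyc <- ceiling(duration / (period - 4 * max(sigma_cycle, 0.01))) + 3
  periods <- pmax(4, rnorm(n_cyc, period, sigma_cycle))
  bounds <- c(0, cumsum(periods))
  cyc <- findInterval(t, bounds)
  phase <- 2 * pi * (cyc - 1 + (t - bounds[cyc]) / periods[cyc])
  tibble::tibble(cell_id = id, time = t,
                 value = sin(phase) + rnorm(length(t), 0, sigma_hf))
}

test_that("noise metrics are near zero for a clean rhythm and grow with noise", {
  clean <- make_noisy_cell("c", 0, 0)
  nm <- noise_metrics(clean)
  expect_lt(nm$cv_period, 0.02)
  expect_lt(nm$cv_amplitude, 0.02)
  expect_lt(nm$hf_noise_ratio, 0.02)

  hf <- vapply(c(0.05, 0.1, 0.2), function(s) {
    noise_metrics(make_noisy_cell("c", s, 0, seed = 3))$hf_noise_ratio
  }, numeric(1))
  expect_true(all(diff(hf) > 0))
})

test_that("cycle-period CV tracks the generating cycle SD", {
  nm <- noise_metrics(make_noisy_cell("c", 0, 1.43, seed = 5, duration = 360))
  expect_gt(nm$n_cycles, 10)
  expect_rel_equal(nm$cv_period, 1.43 / 24, 0.35)
})

test_that("the combined score follows the only varying metric", {
  m <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:10),
    cv_period = 0.05 + 1e-5 * (1:10), cv_amplitude = 0.1 + 1e-5 * (1:10),
    hf_noise_ratio = seq(0.01, 0.2, length.out = 10), n_cycles = 8
  )
  sc <- combined_noise_score(m)
  expect_equal(order(sc$score), order(m$hf_noise_ratio))
})

test_that("score loadings match an eigen-decomposition oracle", {
  set.seed(11)
  m <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:79),
    cv_period = rnorm(79, 0.06, 0.02), cv_amplitude = rnorm(79, 0.2, 0.05),
    hf_noise_ratio = abs(rnorm(79, 0.1, 0.04)), n_cycles = 9
  )
  sc <- combined_noise_score(m)
  x <- scale(as.matrix(m[c("cv_period", "cv_amplitude", "hf_noise_ratio")]))
  ev <- eigen(cor(x))
  v1 <- ev$vectors[, 1]
  if (v1[3] < 0) v1 <- -v1
  expect_equal(unname(abs(attr(sc, "loadings"))), abs(v1), tolerance = 1e-8)
  expect_equal(attr(sc, "prop_var"), ev$values[1] / 3, tolerance = 1e-8)
  expect_lt(abs(mean(sc$score)), 1e-8)
})

test_that("perfectly correlated metrics collapse onto one component", {
  v <- seq(0.01, 0.2, length.out = 12)
  m <- tibble::tibble(cell_id = sprintf("c%02d", 1:12), cv_period = 2 * v,
                      cv_amplitude = 0.5 * v, hf_noise_ratio = v, n_cycles = 8)
  sc <- combined_noise_score(m)
  expect_gt(attr(sc, "prop_var"), 0.999)
  expect_gt(cor(sc$score, v), 0.999)
  expect_error(combined_noise_score(dplyr::mutate(m, cv_period = 0.3)),
               "zero-variance")
})

test_that("group splitting labels the tails and keeps the middle unlabeled", {
  sc <- tibble::tibble(cell_id = sprintf("c%02d", 1:10), score = 1:10)
  g <- split_noise_groups(sc, 3)
  expect_equal(g$noise_group[1:3], rep("low", 3))
  expect_equal(g$noise_group[8:10], rep("high", 3))
  expect_true(all(is.na(g$noise_group[4:7])))

  # 79 cells, 39 per group: exactly one cell stays unlabeled
  sc79 <- tibble::tibble(cell_id = sprintf("c%02d", 1:79), score = rnorm(79))
  g79 <- split_noise_groups(sc79, 39)
  expect_equal(sum(is.na(g79$noise_group)), 1)

  # all-equal scores: deterministic assignment by id order
  tied <- tibble::tibble(cell_id = sprintf("c%02d", 1:6), score = rep(1, 6))
  g1 <- split_noise_groups(tied, 3)
  g2 <- split_noise_groups(tied[sample(1:6), ], 3)
  expect_equal(g1$noise_group[order(g1$cell_id)],
               g2$noise_group[order(g2$cell_id)])
  expect_error(split_noise_groups(sc, 6), "half")
})

test_that("identical sinusoids at random phases re-synchronize on averaging", {
  set.seed(13)
  ts <- 0.5
  t <- seq(0, 200, by = ts)
  traces <- dplyr::bind_rows(lapply(1:12, function(i) {
    tibble::tibble(cell_id = sprintf("c%02d", i), time = t,
                   value = sin(2 * pi * t / 24 + runif(1, 0, 2 * pi)))
  }))
  avg <- align_and_average(traces)
  cs <- cycle_statistics(avg)
  expect_gt(mean(cs$amplitudes), 0.98)     # amplitude loss under 2%
  expect_lt(abs(mean(cs$periods) - 24), 0.3)
})

test_that("the bootstrap is degenerate for identical groups", {
  set.seed(17)
  t <- seq(0, 150, by = 0.5)
  base <- lapply(1:8, function(i) sin(2 * pi * t / 24 + runif(1, 0, 2 * pi)) +
                   rnorm(length(t), 0, 0.05))
  traces <- dplyr::bind_rows(lapply(1:16, function(i) {
    tibble::tibble(cell_id = sprintf("c%02d", i), time = t,
                   value = base[[(i - 1) %% 8 + 1]])
  }))
  groups <- tibble::tibble(cell_id = sprintf("c%02d", 1:16),
                           noise_group = rep(c("low", "high"), each = 8))
  bt <- bootstrap_damping_difference(traces, groups, n_trials = 100, seed = 1)
  expect_lt(bt$observed_stat, 1e-10)
  expect_gt(bt$p_value, 0.9)
})

test_that("period variability decomposition separates the two regimes", {
  t <- seq(0, 240, by = 0.5)
  # identical deterministic cells: both IQRs ~ 0
  same <- dplyr::bind_rows(lapply(1:6, function(i)
    tibble::tibble(cell_id = sprintf("c%02d", i), time = t,
                   value = sin(2 * pi * t / 24))))
  pv <- period_variability_decomposition(same)
  expect_lt(pv$mean_within_iqr, 0.1)
  expect_lt(pv$across_iqr, 0.1)

  # distinct fixed periods, no cycle noise: across > 0, within ~ 0
  per <- seq(22, 26, length.out = 6)
  het <- dplyr::bind_rows(lapply(1:6, function(i)
    tibble::tibble(cell_id = sprintf("c%02d", i), time = t,
                   value = sin(2 * pi * t / per[i]))))
  pv2 <- period_variability_decomposition(het)
  expect_lt(pv2$mean_within_iqr, 0.5)
  expect_gt(pv2$across_iqr, 1)
  expect_equal(pv2$frac_within_exceeds, 0)
})
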