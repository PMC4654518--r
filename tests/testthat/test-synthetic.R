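test_that("generators are pure functions of config and seed", {
  a <- generate_cell_traces(cell_population_config(n_cells = 4, duration = 60),
                            seed = 42)
  b <- generate_cell_traces(cell_population_config(n_cells = 4, duration = 60),
                            seed = 42)
  expect_identical(a, b)

  s1 <- generate_screen(screen_config(n_plates = 2, wells_per_plate = 20),
                        seed = 7)
  s2 <- generate_screen(screen_config(n_plates = 2, wells_per_plate = 20),
                        seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, generate_screen(screen_config(n_plates = 2, wells_per_plate = 20),
                        seed = 8)))
})

test_that("a clean generated series is recovered essentially exactly", {
  d <- generate_damped_series(amplitude = 3, damping = 0.018, period = 23.5,
                              phase = 0.4, ts = 1, n = 120)
  f <- fit_damped_sinusoid(d)
  tr <- attr(d, "truth")
  expect_rel_equal(f$amplitude, tr$amplitude, 1e-4)
  expect_rel_equal(f$damping, tr$damping, 1e-4)
  expect_rel_equal(f$period, tr$period, 1e-4)
})

test_that("an undamped generated series fits near d = 0", {
  d <- generate_damped_series(amplitude = 2, damping = 0, period = 24,
                              ts = 1, n = 120, noise_sd = 0.02, seed = 3)
  f <- fit_damped_sinusoid(d, fit_config(refine = FALSE))
  expect_lt(abs(f$damping), 0.002)
})

test_that("noisy generated series are recovered within a few percent (median over seeds)", {
  errs <- vapply(1:20, function(s) {
    d <- generate_damped_series(amplitude = 2, damping = 0.02, period = 24,
                                phase = 0.5, ts = 1, n = 192,
                                noise_sd = 0.2, seed = s)
    f <- fit_damped_sinusoid(d)
    c(abs(f$damping - 0.02) / 0.02, abs(f$period - 24) / 24)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("generated cell populations reproduce the variability regime", {
  tr <- generate_cell_traces(
    cell_population_config(n_cells = 15, duration = 260), seed = 21)
  pv <- period_variability_decomposition(tr)
  expect_gt(pv$mean_within_iqr, pv$across_iqr)

  # zero-noise config: pure sinusoids with distinct fixed periods
  tr0 <- generate_cell_traces(
    cell_population_config(n_cells = 6, duration = 200, sd_within = 0,
                           amplitude_cv = 0, hf_noise_sd = 0,
                           drift_scale = 0), seed = 5)
  pv0 <- period_variability_decomposition(tr0)
  expect_lt(pv0$mean_within_iqr, 0.2)
})

test_that("noisier populations earn higher combined noise scores", {
  quiet <- generate_cell_traces(
    cell_population_config(n_cells = 12, duration = 240, sd_within = 0.7,
                           hf_noise_sd = 0.05, amplitude_cv = 0.1), seed = 2)
  noisy <- generate_cell_traces(
    cell_population_config(n_cells = 12, duration = 240, sd_within = 1.4,
                           hf_noise_sd = 0.1, amplitude_cv = 0.2), seed = 2)
  noisy <- dplyr::mutate(noisy, cell_id = paste0("n_", cell_id))
  nm <- noise_metrics(dplyr::bind_rows(quiet, noisy))
  sc <- combined_noise_score(nm)
  is_noisy <- grepl("^n_", sc$cell_id)
  # AUC of score separating the two populations
  r <- rank(sc$score)
  auc <- (sum(r[is_noisy]) - sum(is_noisy) * (sum(is_noisy) + 1) / 2) /
    (sum(is_noisy) * sum(!is_noisy))
  expect_gt(auc, 0.9)
})

test_that("generated screens have the declared structure", {
  cfg <- screen_config(n_plates = 3, wells_per_plate = 40, n = 72, ts = 2)
  s <- generate_screen(cfg, seed = 10)
  expect_equal(nrow(s), 120)
  expect_equal(sum(grepl("^t\\d+$", names(s))), 72)
  expect_equal(attr(s, "times"), 2 * (0:71))
  expect_equal(sum(s$category == "control"), 12)
  genes <- table(s$gene_id[!is.na(s$gene_id)])
  expect_true(all(genes <= 4))
})
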