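zrob <- function(v) (v - median(v)) / median(abs(v - median(v)))

make_records <- function(z, plate = "p1", category = "control") {
  n <- length(z)
  tibble::tibble(
    plate_id = plate, well_pos = sprintf("w%03d", seq_len(n)),
    gene_id = NA_character_, category = category,
    amplitude = exp(z), ln_amplitude = z, damping = z, period = z,
    phase = rep(0, n), r_squared = 0.95, qc_pass = TRUE
  )
}

test_that("robust z-scores reproduce the hand-computed cases", {
  expect_equal(zrob(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zrob(c(1, 2, 3, 4, 100)), c(-2, -1, 0, 1, 97))

  rec <- make_records(c(1, 2, 3, 4, 100))
  vary <- c("period", "ln_amplitude", "damping")  # phase is constant here
  norm <- plate_normalize(rec, params = vary)
  expect_equal(norm$z_damping, c(-2, -1, 0, 1, 97))

  # affine transforms with positive scale leave z-scores unchanged
  rec2 <- dplyr::mutate(rec, damping = 3 + 2.5 * damping)
  expect_equal(plate_normalize(rec2, params = vary)$z_damping, norm$z_damping)
  # negation flips the sign
  rec3 <- dplyr::mutate(rec, damping = -damping)
  expect_equal(plate_normalize(rec3, params = vary)$z_damping, -norm$z_damping)
})

test_that("zero median absolute deviation is flagged, not propagated", {
  rec <- make_records(c(1, 1, 1, 1, 2))
  expect_warning(norm <- plate_normalize(rec, params = "damping"),
                 "zero median absolute deviation")
  expect_true(all(is.na(norm$z_damping)))
})

test_that("a plate of exact damped sinusoids passes QC completely", {
  cfg <- screen_config(n_plates = 1, wells_per_plate = 30,
                       arrhythmic_fraction = 0, noise_sd = 0)
  s <- generate_screen(cfg, seed = 3)
  rec <- batch_fit_and_qc(s, ts = 2)
  expect_equal(unname(attr(rec, "counts")["n_qc"]), 30L)
  expect_true(all(rec$qc_pass))
  truth <- attr(s, "truth")$params
  expect_lt(median(abs(rec$period - truth$period)), 0.1)
})

test_that("arrhythmic wells are caught by the R-squared filter", {
  cfg <- screen_config(n_plates = 2, wells_per_plate = 50,
                       arrhythmic_fraction = 0.15, control_fraction = 0.02)
  s <- generate_screen(cfg, seed = 14)
  rec <- batch_fit_and_qc(s, ts = 2)
  truth <- attr(s, "truth")$params
  arr_rate <- mean(truth$arrhythmic)
  pass <- mean(rec$qc_pass)
  expect_lt(abs((1 - pass) - arr_rate), 0.06)
  # arrhythmic wells should dominate the failures
  expect_gt(mean(truth$arrhythmic[!rec$qc_pass]), 0.7)
})

test_that("moments of standard-normal z columns are recovered", {
  set.seed(31)
  n <- 10000
  rec <- tibble::tibble(
    plate_id = "p1", well_pos = sprintf("w%05d", 1:n),
    gene_id = NA_character_, category = rep(c("control", "perturbed"), n / 2),
    qc_pass = TRUE,
    z_period = rnorm(n), z_ln_amplitude = rnorm(n),
    z_damping = rnorm(n), z_phase = rnorm(n)
  )
  sm <- summarize_distributions(rec)
  mo <- sm$moments
  expect_true(all(abs(mo$mean) < 0.1))
  expect_true(all(abs(mo$variance - 1) < 0.1))
  expect_true(all(abs(mo$skewness) < 0.1))
  expect_true(all(abs(mo$ex_kurtosis) < 0.15))
  expect_true(all(abs(sm$correlations[upper.tri(sm$correlations)]) < 0.05))
  expect_equal(diag(sm$correlations), rep(1, 4), ignore_attr = TRUE)
})

test_that("built-in correlation between amplitude and damping is recovered", {
  set.seed(33)
  n <- 10000
  a <- rnorm(n)
  d <- 0.3 * a + sqrt(1 - 0.3^2) * rnorm(n)
  rec <- tibble::tibble(
    plate_id = "p1", well_pos = sprintf("w%05d", 1:n),
    gene_id = NA_character_, category = "perturbed", qc_pass = TRUE,
    z_period = rnorm(n), z_ln_amplitude = a, z_damping = d, z_phase = rnorm(n)
  )
  sm <- summarize_distributions(rec)
  expect_lt(abs(sm$correlations["ln_amplitude", "damping"] - 0.3), 0.05)
})

test_that("single extreme z-scores are excluded as outliers", {
  rec <- tibble::tibble(
    plate_id = "p1", well_pos = sprintf("w%03d", 1:100),
    gene_id = NA_character_, category = "control", qc_pass = TRUE,
    z_period = c(9, rnorm(99)), z_ln_amplitude = rnorm(100),
    z_damping = rnorm(100), z_phase = rnorm(100)
  )
  sm <- summarize_distributions(rec)
  expect_equal(unname(sm$counts["n_outlier"]), 1L)
  expect_true(sm$records$outlier[1])
  expect_equal(unname(sm$counts["n_kept"]), 99L)
})

test_that("the damping regression recovers null and signal cases", {
  set.seed(35)
  n <- 10000
  base <- tibble::tibble(
    plate_id = "p1", well_pos = sprintf("w%05d", 1:n),
    gene_id = NA_character_, category = rep(c("control", "perturbed"), n / 2),
    qc_pass = TRUE, outlier = FALSE,
    z_period = rnorm(n), z_ln_amplitude = rnorm(n), z_phase = rnorm(n)
  )
  null_rec <- dplyr::mutate(base, z_damping = rnorm(n))
  rn <- regress_damping(null_rec)
  expect_lt(rn$r_squared, 0.01)

  sig_rec <- dplyr::mutate(base, z_damping = 0.3 * z_ln_amplitude + rnorm(n))
  rs <- regress_damping(sig_rec)
  co <- rs$coefficients
  est <- co$estimate[co$term == "z_ln_amplitude"]
  expect_lt(abs(est - 0.3), 0.03)
  expect_true("perturbed" %in% co$term)
})

test_that("Hotelling T2 is zero at the control center and calibrated under the null", {
  set.seed(37)
  n_ctrl <- 4000
  ctrl <- tibble::tibble(
    plate_id = "p1", well_pos = sprintf("c%05d", 1:n_ctrl),
    gene_id = NA_character_, category = "control", qc_pass = TRUE,
    z_period = rnorm(n_ctrl), z_ln_amplitude = rnorm(n_ctrl),
    z_damping = rnorm(n_ctrl), z_phase = rnorm(n_ctrl)
  )
  n_genes <- 400
  pert <- tibble::tibble(
    plate_id = "p1", well_pos = sprintf("g%05d", 1:(4 * n_genes)),
    gene_id = rep(sprintf("gene_%04d", 1:n_genes), each = 4),
    category = "perturbed", qc_pass = TRUE,
    z_period = rnorm(4 * n_genes), z_ln_amplitude = rnorm(4 * n_genes),
    z_damping = rnorm(4 * n_genes), z_phase = rnorm(4 * n_genes)
  )
  res <- gene_group_test(dplyr::bind_rows(ctrl, pert), alpha = 0.01)
  expect_equal(nrow(res), n_genes)
  # null rejection rate near alpha
  expect_gt(mean(res$significant), 0.001)
  expect_lt(mean(res$significant), 0.04)

  # a gene exactly at the robust control center scores T2 ~ 0
  center <- attr(res, "center")
  at_center <- tibble::tibble(
    plate_id = "p1", well_pos = sprintf("x%d", 1:4),
    gene_id = "gene_center", category = "perturbed", qc_pass = TRUE,
    z_period = rep(center[1], 4), z_ln_amplitude = rep(center[2], 4),
    z_damping = rep(center[3], 4), z_phase = rep(center[4], 4)
  )
  res2 <- gene_group_test(dplyr::bind_rows(ctrl, at_center))
  row <- res2[res2$gene_id == "gene_center", ]
  expect_lt(row$t2, 0.5)
  expect_gt(row$p_value, 0.9)
})

test_that("Hotelling T2 is invariant under joint affine transforms", {
  set.seed(39)
  n_ctrl <- 2000
  zc <- matrix(rnorm(n_ctrl * 4), ncol = 4)
  zg <- matrix(rnorm(16, mean = 1), ncol = 4)
  build <- function(m_ctrl, m_gene) {
    dplyr::bind_rows(
      tibble::tibble(plate_id = "p", well_pos = sprintf("c%d", 1:nrow(m_ctrl)),
                     gene_id = NA_character_, category = "control",
                     qc_pass = TRUE,
                     z_period = m_ctrl[, 1], z_ln_amplitude = m_ctrl[, 2],
                     z_damping = m_ctrl[, 3], z_phase = m_ctrl[, 4]),
      tibble::tibble(plate_id = "p", well_pos = sprintf("g%d", 1:nrow(m_gene)),
                     gene_id = "g1", category = "perturbed", qc_pass = TRUE,
                     z_period = m_gene[, 1], z_ln_amplitude = m_gene[, 2],
                     z_damping = m_gene[, 3], z_phase = m_gene[, 4])
    )
  }
  t2_a <- gene_group_test(build(zc, zg))$t2
  aff <- matrix(c(2, 0.3, 0, 0, 0.1, 1.5, 0, 0,
                  0, 0.2, 0.8, 0, 0, 0, 0.4, 1.2), 4, 4)
  shift <- c(1, -2, 0.5, 3)
  tr <- function(m) sweep(m %*% aff, 2, shift, "+")
  t2_b <- gene_group_test(build(tr(zc), tr(zg)))$t2
  expect_equal(t2_a, t2_b, tolerance = 0.15)   # MCD subset selection jitters slightly
})

test_that("quadrant fractions and the radial histogram behave", {
  g <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10), n = 4, t2 = 50, p_value = 1e-6,
    shift_period = 0, shift_phase = 0,
    shift_ln_amplitude = -abs(rnorm(10)), shift_damping = abs(rnorm(10)),
    significant = TRUE
  )
  q <- quadrant_fractions(g)
  expect_equal(q$fractions$fraction[q$fractions$quadrant == "lower_A_higher_d"], 1)
  expect_equal(sum(q$fractions$fraction), 1)
  expect_equal(sum(q$histogram$n), 10)

  set.seed(43)
  iso <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10000), n = 4, t2 = 50, p_value = 1e-6,
    shift_period = 0, shift_phase = 0,
    shift_ln_amplitude = rnorm(10000), shift_damping = rnorm(10000),
    significant = TRUE
  )
  qi <- quadrant_fractions(iso)
  expect_true(all(abs(qi$fractions$fraction - 0.25) < 0.02))
})
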