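test_that("the same config and seed reproduce an identical cohort", {
  a <- generate_cohort(cohort_config(seed = 77))
  b <- generate_cohort(cohort_config(seed = 77))
  expect_identical(a$records, b$records)
  expect_identical(a$truth$patients, b$truth$patients)
  c2 <- generate_cohort(cohort_config(seed = 78))
  expect_false(identical(a$records, c2$records))
})

test_that("cohort structure honours the configured invariants", {
  coh <- generate_cohort(cohort_config(seed = 4))
  rec <- coh$records
  expect_equal(dplyr::n_distinct(rec$patient_id), 8)
  per_patient <- dplyr::count(rec, patient_id)
  expect_true(all(per_patient$n >= 2 & per_patient$n <= 6))
  expect_true(all(dplyr::count(rec, shock_type)$n > 0))
  num_cols <- c("tewl_forehead", "tewl_upper_limb", "tewl_lower_limb",
                "tewl_trunk", "parenteral_ml", "enteral_ml", "urine_ml",
                "ultrafiltrate_ml")
  for (cc in num_cols) expect_true(all(rec[[cc]] >= 0))
  # days are 1..n within each patient
  days <- tapply(rec$day, rec$patient_id, function(d) all(d == seq_along(d)))
  expect_true(all(days))
  # one patient per arm lacks SVRI by default
  missing_by_arm <- tapply(rec$svri, rec$shock_type,
                           function(x) any(is.na(x)))
  expect_true(all(missing_by_arm))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_septic = 0, n_cardiogenic = 0), "n_septic")
  expect_error(cohort_config(days_min = 0), "days_min")
  expect_error(cohort_config(days_min = 5, days_max = 3), "days_min")
  expect_error(cohort_config(coupling_noise_sd = -1), "SD")
  expect_error(cohort_config(forehead_multiplier = 0),
               "forehead_multiplier")
  expect_error(cohort_config(day_ar1 = 1), "day_ar1")
  expect_error(
    cohort_config(fluid_params = list(septic = list(), cardiogenic = list())),
    "fluid_params")
})

test_that("forehead site is elevated by the configured multiplier", {
  coh <- big_cohort(seed = 8, n_septic = 150, n_cardiogenic = 90)
  base <- coh$truth$patients
  expect_equal(mean(base$base_forehead) / mean(base$base_trunk), 1.553,
               tolerance = 0.1)
  expect_gt(mean(coh$records$tewl_forehead), mean(coh$records$tewl_trunk))
})

test_that("arm-level fluid structure follows the configured directionality", {
  coh <- big_cohort(seed = 14, n_septic = 60, n_cardiogenic = 60)
  rec <- coh$records
  par_means <- tapply(rec$parenteral_ml, rec$shock_type, mean)
  uf_means <- tapply(rec$ultrafiltrate_ml, rec$shock_type, mean)
  svri_means <- tapply(rec$svri, rec$shock_type, mean)
  expect_gt(par_means[["septic"]], par_means[["cardiogenic"]])
  expect_gt(uf_means[["cardiogenic"]], uf_means[["septic"]])
  expect_lt(svri_means[["septic"]], svri_means[["cardiogenic"]])
})

test_that("a zero coupling slope yields a near-zero downstream slope", {
  slopes <- vapply(1:5, function(s) {
    coh <- big_cohort(seed = s, coupling_slope_beta = 0,
                      coupling_noise_sd = 2)
    tewl_svri_regression(coh$records)$slope
  }, numeric(1))
  expect_true(all(abs(slopes) < 0.1))
})

test_that("more negative generator coupling gives a more negative fitted slope", {
  mean_slope <- function(beta) {
    mean(vapply(1:10, function(s) {
      coh <- big_cohort(seed = s, coupling_slope_beta = beta)
      tewl_svri_regression(coh$records)$slope
    }, numeric(1)))
  }
  slopes <- vapply(c(0, -0.5, -1), mean_slope, numeric(1))
  expect_true(all(diff(slopes) < 0))
})

test_that("sensor streams are seeded, degenerate-safe, and converge in truth", {
  flat <- generate_sensor_stream(10, noise_sd = 0, drift_per_s = 0,
                                 duration_s = 30)
  expect_equal(flat$tewl, rep(10, 30))
  s1 <- generate_sensor_stream(10, duration_s = 100, seed = 5)
  s2 <- generate_sensor_stream(10, duration_s = 100, seed = 5)
  expect_identical(s1, s2)
  expect_error(generate_sensor_stream(10, duration_s = 0), ">= 1")
  expect_error(generate_sensor_stream(10, noise_sd = -0.1), ">= 0")
  out <- stabilize_tewl(generate_sensor_stream(10, seed = 99)$tewl)
  expect_true(out$converged)
  expect_lt(abs(out$stable_value - 10), 0.2)
})

test_that("a cohort can be written to disk with its truth sidecar", {
  dir <- withr::local_tempdir()
  coh <- demo_cohort(seed = 55)
  paths <- write_cohort(coh, dir)
  expect_true(file.exists(paths$records))
  expect_true(file.exists(paths$truth))
  truth <- yaml::read_yaml(paths$truth)
  expect_equal(truth$seed, 55)
  expect_equal(truth$coupling_slope_beta, -1)
  back <- readr::read_csv(paths$records, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(coh$records))
})
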