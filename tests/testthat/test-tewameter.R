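test_that("Magnus saturation pressure matches hand-computed values and is monotone", {
  expect_equal(saturation_vapor_pressure(0), 6.112, tolerance = 1e-9)
  # 6.112 * exp(17.62 * 20 / 263.12), evaluated independently
  expect_equal(saturation_vapor_pressure(20), 23.32596022, tolerance = 1e-7)
  expect_gt(saturation_vapor_pressure(25), saturation_vapor_pressure(20))
  temps <- seq(-30, 55, by = 5)
  expect_true(all(diff(saturation_vapor_pressure(temps)) > 0))
  expect_error(saturation_vapor_pressure(75), "within")
})

test_that("vapor density follows the ideal-gas conversion and is linear in RH", {
  expect_identical(vapor_density(0, 25), 0)
  expect_identical(vapor_density(0, -10), 0)
  # e_s(25) * 100 Pa / (461.5 * 298.15 K), in g/m^3, hand-checked
  expect_equal(vapor_density(100, 25), 22.96615998, tolerance = 1e-7)
  expect_equal(vapor_density(50, 25), vapor_density(100, 25) / 2,
               tolerance = 1e-12)
  expect_error(vapor_density(-5, 25), "percent")
  expect_error(vapor_density(105, 25), "percent")
})

test_that("Fick's-law flux reproduces the hand arithmetic oracle", {
  # choose RH at 25 C on both sensors so the densities are exactly 15 and
  # 14 g/m^3; then J = 2.49e-5 * (15 - 14) / 0.005 * 3600 = 17.928 g/h/m^2
  vd_sat <- vapor_density(100, 25)
  r <- suppressWarnings(sensor_pair_reading(
    rh_lower = 100 * 15 / vd_sat, rh_upper = 100 * 14 / vd_sat,
    temp_lower = 25, temp_upper = 25
  ))
  expect_equal(tewl_from_gradient(r), 17.928, tolerance = 1e-6)
})

test_that("flux is zero without a gradient, negates on sensor swap, and is linear", {
  same <- sensor_pair_reading(50, 50, 25, 25)
  expect_identical(tewl_from_gradient(same), 0)
  fwd <- sensor_pair_reading(60, 45, 30, 28)
  rev <- sensor_pair_reading(45, 60, 28, 30)
  expect_equal(tewl_from_gradient(fwd), -tewl_from_gradient(rev),
               tolerance = 1e-12)
  # doubling the density gradient doubles the flux (all at one temperature)
  g1 <- sensor_pair_reading(50, 45, 25, 25)
  g2 <- sensor_pair_reading(55, 45, 25, 25)
  expect_equal(tewl_from_gradient(g2), 2 * tewl_from_gradient(g1),
               tolerance = 1e-12)
  # and flux scales with the diffusion coefficient
  expect_equal(tewl_from_gradient(fwd, diffusion_coeff = 4.98e-5),
               2 * tewl_from_gradient(fwd), tolerance = 1e-12)
})

test_that("sensor readings are validated and range violations warn", {
  expect_error(sensor_pair_reading(120, 50, 25, 25), "0, 100")
  expect_error(sensor_pair_reading(50, 50, 25, 25, height_lower = 0.008,
                                   height_upper = 0.003),
               "height_upper > height_lower")
  expect_warning(r <- sensor_pair_reading(80, 50, 25, 25), "operating range")
  expect_false(r$in_range)
  bad <- sensor_pair_reading(50, 45, 25, 25)
  bad$height_upper <- bad$height_lower
  expect_error(tewl_from_gradient(bad), "separation")
})

test_that("stabilization stops immediately on a constant stream", {
  out <- stabilize_tewl(rep(10, 60), window = 10)
  expect_true(out$converged)
  expect_equal(out$stable_value, 10)
  expect_equal(out$time_to_stability_s, 10)
  expect_equal(out$sd_at_stop, 0)
})

test_that("an alternating stream never satisfies the criterion", {
  out <- stabilize_tewl(rep(c(0, 20), 120), window = 10)
  expect_false(out$converged)
  expect_equal(out$time_to_stability_s, 240)
  expect_gt(out$sd_at_stop, 5)
  # non-convergence is a flagged result, not an exception, and still
  # carries the last running mean
  expect_true(is.finite(out$stable_value))
})

test_that("stabilization converges near truth on simulated decaying-drift streams", {
  for (s in c(1, 7, 42)) {
    st <- generate_sensor_stream(10, noise_sd = 0.05, drift_per_s = 1.0,
                                 duration_s = 240, seed = s)
    out <- stabilize_tewl(st$tewl)
    expect_true(out$converged)
    expect_lt(abs(out$stable_value - 10), 0.2)
  }
})

test_that("reversing a convergent noisy stream moves the stable value by less than the threshold", {
  diffs <- vapply(1:100, function(s) {
    st <- generate_sensor_stream(10, noise_sd = 0.05, drift_per_s = 0,
                                 duration_s = 120, seed = s)
    abs(stabilize_tewl(st$tewl)$stable_value -
          stabilize_tewl(rev(st$tewl))$stable_value)
  }, numeric(1))
  expect_true(all(diffs < 0.2))
})

test_that("stabilization validates its inputs and supports the cumulative mode", {
  expect_error(stabilize_tewl(numeric(0)), "non-empty")
  expect_error(stabilize_tewl(1:20, sd_threshold = 0), "> 0")
  expect_error(stabilize_tewl(1:20, window = 1), ">= 2")
  out <- stabilize_tewl(rep(5, 40), mean_mode = "cumulative")
  expect_true(out$converged)
  expect_equal(out$stable_value, 5)
})

test_that("raw stream files round-trip through both accepted column layouts", {
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(seconds = 1:5, tewl = c(10, 10.1, 10, 9.9, 10)), tmp2)
  s2 <- read_tewl_stream(tmp2)
  expect_named(s2, c("seconds", "tewl"))
  expect_equal(nrow(s2), 5)

  tmp6 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    seconds = 1:3, rh_lower = c(60, 61, 60), rh_upper = 45,
    temp_lower = 30, temp_upper = 28
  ), tmp6)
  s6 <- read_tewl_stream(tmp6)
  expect_equal(nrow(s6), 3)
  expect_true(all(s6$tewl > 0))

  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(a = 1), bad)
  expect_error(read_tewl_stream(bad), "columns")
})
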