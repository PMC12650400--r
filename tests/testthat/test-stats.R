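test_that("the normality gate accepts normal samples and rejects skewed ones", {
  pass <- vapply(1:100, function(s) {
    set.seed(s)
    normality_check(rnorm(200))$normal
  }, logical(1))
  expect_gte(mean(pass), 0.9)
  fail <- vapply(1:100, function(s) {
    set.seed(s + 1000)
    !normality_check(rexp(200))$normal
  }, logical(1))
  expect_gte(mean(fail), 0.9)
})

test_that("degenerate and undersized samples are handled explicitly", {
  const <- normality_check(rep(3, 10))
  expect_false(const$normal)
  expect_true(const$zero_variance)
  expect_error(normality_check(c(1, 2, 3)), "at least 4")
  # Lilliefors variant is selectable
  set.seed(1)
  expect_true(normality_check(rnorm(100), method = "lilliefors")$normal)
})

test_that("compare_groups gates the test on normality and flags identical groups", {
  set.seed(42)
  a <- rnorm(50)
  b <- rnorm(50, 1)
  cg <- compare_groups(a, b)
  expect_equal(cg$test_used, "welch_t")
  expect_lt(cg$p_value, 0.01)
  # heavily skewed data routes to the rank test
  cg2 <- compare_groups(exp(rnorm(60, 0, 1.5)), exp(rnorm(60, 0.2, 1.5)))
  expect_equal(cg2$test_used, "mann_whitney")
  same <- suppressWarnings(compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_true(same$degenerate)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  td <- tidy(cg)
  expect_equal(nrow(td), 2)
  expect_equal(td$mean, c(cg$mean_a, cg$mean_b))
})

test_that("the paired method test matches exact signed-rank enumeration", {
  # a uniform +100 shift over 12 pairs: the all-positive-ranks extreme,
  # two-sided exact p = 2 / 2^12
  set.seed(7)
  tewl <- rnorm(12, 400, 50)
  res <- compare_methods_paired(tewl + 100, tewl)
  expect_equal(res$p_value, 2 / 2^12, tolerance = 1e-12)
  expect_equal(res$n_pairs, 12)
  expect_equal(res$median_difference, 100, tolerance = 1e-9)
  expect_error(compare_methods_paired(tewl, tewl), "degenerate")
  expect_error(compare_methods_paired(1:3, 4:5), "equal length")
})

test_that("the exact sign-flip enumeration agrees with the classical exact test on untied data", {
  for (s in 1:10) {
    set.seed(s)
    tewl <- rnorm(15, 400, 80)
    formula <- tewl + rnorm(15, 60, 120)
    ours <- compare_methods_paired(formula, tewl)
    ref <- stats::wilcox.test(formula, tewl, paired = TRUE, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("the paired test has power at a 26-pair cohort with a 150 mL shift", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    tewl <- rnorm(26, 350, 200)
    formula <- tewl + 150 + rnorm(26, 0, 200)
    compare_methods_paired(formula, tewl)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("step-down Sidak adjustment matches hand evaluation and dominates raw p", {
  expect_equal(holm_sidak_adjust(0.03), 0.03)
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone non-decreasing in rank order of the raw p's
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_sidak_adjust(c(0.2, 1.3)), "0, 1")
})

test_that("site ANOVA detects the elevated forehead and reports all pairs", {
  coh <- big_cohort(seed = 5)
  res <- site_anova_holm_sidak(coh$records)
  expect_equal(nrow(res$pairwise), 6)
  expect_lt(res$anova$p_value, 0.05)
  fh_trunk <- res$pairwise[
    (res$pairwise$site_a == "forehead" & res$pairwise$site_b == "trunk") |
      (res$pairwise$site_a == "trunk" & res$pairwise$site_b == "forehead"), ]
  expect_lt(fh_trunk$p_adjusted, 0.05)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
  expect_error(site_anova_holm_sidak(tiny_records()[1:2, ]), "at least 3")
})

test_that("simple regression recovers exact fits and rejects degenerate input", {
  fit <- suppressWarnings(fit_regression(1:10, 2 * (1:10) + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(3)
  null_fit <- fit_regression(rnorm(1000), rnorm(1000))
  expect_lt(null_fit$r_squared, 0.01)
  expect_error(fit_regression(rep(1, 10), rnorm(10)), "constant")
  expect_error(fit_regression(1:2, 1:2), "at least 3")
  g <- glance(fit)
  expect_named(g, c("slope", "intercept", "r.squared", "p.value", "n"))
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate, c(1, 2), tolerance = 1e-10)
})

test_that("R-squared is invariant to affine rescaling of both axes", {
  set.seed(9)
  x <- rnorm(60)
  y <- -x + rnorm(60)
  f0 <- fit_regression(x, y)
  f1 <- fit_regression(10 + 3 * x, -2 + 0.5 * y)
  expect_equal(f1$r_squared, f0$r_squared, tolerance = 1e-12)
})

test_that("slope recovery at a 19-pair scale stays within the stated band", {
  set.seed(21)
  slopes <- vapply(1:100, function(i) {
    x <- rnorm(19, 100, 25)
    y <- 100 - (x - 100) + rnorm(19, 0, 25)  # true slope -1, R^2 ~ 0.5
    fit_regression(x, y)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 1), 0.35)
})

test_that("percent-of-mean normalization gives each patient mean 100", {
  d <- tibble::tibble(patient_id = c("a", "a"), v = c(8, 12))
  out <- normalize_to_patient_mean(d, v)
  expect_equal(out$v_pct, c(80, 120))
  single <- normalize_to_patient_mean(
    tibble::tibble(patient_id = "z", v = 7.3), v)
  expect_equal(single$v_pct, 100)
  coh <- demo_cohort()
  norm <- coh$records |>
    dplyr::mutate(wb = rule_of_nines_tewl(tewl_forehead, tewl_upper_limb,
                                          tewl_lower_limb, tewl_trunk)) |>
    normalize_to_patient_mean(wb)
  per_patient <- as.numeric(tapply(norm$wb_pct, norm$patient_id, mean))
  expect_equal(per_patient, rep(100, length(per_patient)),
               tolerance = 1e-9)
  zero <- tibble::tibble(patient_id = "q", v = c(0, 0))
  expect_error(normalize_to_patient_mean(zero, v), "zero")
})

test_that("deviation regression carries the forced sign of a constant formula", {
  est <- tibble::tibble(
    tewl_ml_per_24h = seq(100, 700, length.out = 20),
    formula_ml_per_24h = 400
  )
  est$relative_deviation_pct <- relative_deviation(est$formula_ml_per_24h,
                                                   est$tewl_ml_per_24h)
  fit <- deviation_regression(est)
  expect_lt(fit$slope, 0)
  # proportional estimators: constant deviation, zero slope
  prop <- dplyr::mutate(est, formula_ml_per_24h = 1.25 * tewl_ml_per_24h,
                        relative_deviation_pct = 25)
  flat <- suppressWarnings(deviation_regression(prop))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
})

test_that("the normalized TEWL-SVRI fit separates absolute and normalized scales", {
  coh <- demo_cohort(seed = 31)
  fit <- tewl_svri_regression(coh$records)
  expect_equal(fit$scale, "percent_of_patient_mean")
  expect_lt(fit$slope, 0)
  abs_fit <- tewl_svri_regression(coh$records, absolute = TRUE)
  expect_equal(abs_fit$scale, "absolute")
  # SVRI-free input fails loudly
  no_svri <- dplyr::mutate(coh$records, svri = NA_real_)
  expect_error(tewl_svri_regression(no_svri), "no records with SVRI")
})
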