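#' Normality gate for test selection
#'
#' One-sample Kolmogorov--Smirnov test of a sample against a normal
#' distribution with the sample's own mean and SD (the "as appropriate"
#' gate used to choose between parametric and rank tests). Estimating the
#' parameters from the same sample makes the plain KS p-value
#' anti-conservative; the Lilliefors correction is selectable via
#' `method = "lilliefors"` (requires the nortest package).
#'
#' @param x Numeric sample, n >= 4.
#' @param alpha Significance level of the gate (default 0.05); the sample
#'   "fails" normality when p < alpha.
#' @param method `"ks"` (default) or `"lilliefors"`.
#' @return A one-row tibble: `n`, `statistic`, `p_value`, `normal`
#'   (logical), `zero_variance` (logical; a constant sample is reported as
#'   non-normal with this flag set).
#' @export
normality_check <- function(x, alpha = 0.05, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 4) {
    stop("normality check needs at least 4 observations", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    return(tibble::tibble(n = length(x), statistic = NA_real_,
                          p_value = 0, normal = FALSE,
                          zero_variance = TRUE))
  }
  res <- if (method == "ks") {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  } else {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("method = \"lilliefors\" requires the nortest package",
           call. = FALSE)
    }
    nortest::lillie.test(x)
  }
  tibble::tibble(n = length(x), statistic = unname(res$statistic),
                 p_value = res$p.value, normal = res$p.value >= alpha,
                 zero_variance = FALSE)
}

#' Two-group comparison with a normality-gated test choice
#'
#' Compares two independent samples with Welch's t-test when both pass the
#' normality gate ([normality_check()]) at level `alpha`, and with the
#' two-sided Mann--Whitney U test otherwise. Ties in the rank test are
#' handled by mid-ranks with the normal approximation when an exact p is
#' unavailable. The test actually used is recorded in the result.
#'
#' @param a,b Numeric samples, each n >= 2 (n >= 4 for the gate to run; with
#'   fewer than 4 observations in a group the rank test is used).
#' @param alpha Significance level of the normality gate.
#' @param normality_method Passed to [normality_check()].
#' @return A one-row tibble of class `tewl_group_comparison`: group means,
#'   SDs and sizes, `test_used` (`"welch_t"` or `"mann_whitney"`),
#'   `p_value`, and `degenerate` (TRUE when the two samples are identical
#'   multisets, where the rank test carries no information).
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           normality_method = c("ks", "lilliefors")) {
  normality_method <- match.arg(normality_method)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  degenerate <- identical(sort(a), sort(b))
  gate <- function(x) {
    length(x) >= 4 && stats::sd(x) > 0 &&
      normality_check(x, alpha = alpha, method = normality_method)$normal
  }
  use_t <- gate(a) && gate(b)
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    test_used <- "welch_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                              correct = TRUE))
    test_used <- "mann_whitney"
  }
  out <- tibble::tibble(
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    test_used = test_used, p_value = ht$p.value, degenerate = degenerate
  )
  class(out) <- c("tewl_group_comparison", class(out))
  out
}

#' Paired comparison of the two skin-loss estimators
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test on the per-record
#' differences between formula-based and TEWL-based 24-h losses. Zero
#' differences are dropped; the absolute differences are mid-ranked (so
#' ties are permitted). For up to 25 non-zero differences the p-value is
#' exact, computed by full enumeration of the 2^n sign-flip null
#' distribution; beyond that the normal approximation with continuity
#' correction is used.
#'
#' @param formula_ml,tewl_ml Equal-length numeric vectors of paired
#'   estimates (mL/24 h).
#' @param min_nonzero Minimum number of non-zero differences required
#'   (default 5).
#' @return A one-row tibble: `n_pairs`, `n_nonzero`, `median_formula`,
#'   `median_tewl`, `median_difference`, `statistic` (the positive-rank sum
#'   V), `p_value`, `exact` (logical).
#' @export
compare_methods_paired <- function(formula_ml, tewl_ml, min_nonzero = 5) {
  if (length(formula_ml) != length(tewl_ml)) {
    stop("paired series must have equal length", call. = FALSE)
  }
  keep <- !is.na(formula_ml) & !is.na(tewl_ml)
  formula_ml <- formula_ml[keep]
  tewl_ml <- tewl_ml[keep]
  d <- formula_ml - tewl_ml
  if (all(d == 0)) {
    stop("all paired differences are zero; signed-rank test is degenerate",
         call. = FALSE)
  }
  dnz <- d[d != 0]
  n <- length(dnz)
  if (n < min_nonzero) {
    stop("fewer than ", min_nonzero, " non-zero paired differences",
         call. = FALSE)
  }
  r <- rank(abs(dnz))
  v <- sum(r[dnz > 0])
  exact <- n <= 25
  p <- if (exact) {
    .signed_rank_exact_p(r, v)
  } else {
    # normal approximation with tie-corrected variance and continuity
    # correction (the mid-rank large-sample route)
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu - sign(v - mu) * 0.5) / sigma
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  tibble::tibble(
    n_pairs = length(d), n_nonzero = n,
    median_formula = stats::median(formula_ml),
    median_tewl = stats::median(tewl_ml),
    median_difference = stats::median(d),
    statistic = v, p_value = p, exact = exact
  )
}

# exact two-sided sign-flip p-value for the signed-rank statistic with
# mid-ranks: the null distribution of 2V (doubled ranks are integers) is
# built by polynomial convolution over the 2^n equiprobable sign vectors
.signed_rank_exact_p <- function(ranks, v) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # dist[k + 1] = number of sign vectors with doubled statistic k
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (rr in r2) {
    shifted <- c(numeric(rr), dist[seq_len(total + 1 - rr)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(dist[seq_len(v2 + 1)])
  p_ge <- sum(dist[(v2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Step-down Sidak (Holm-Sidak) p-value adjustment
#'
#' Orders the m raw p-values ascending and adjusts the i-th smallest as
#' \eqn{\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m - i + 1}}, then enforces
#' monotone non-decreasing adjusted values (and caps at 1). With m = 1 the
#' p-value is returned unchanged. This is the step-down analogue of the
#' Sidak single-step correction, slightly more powerful than Holm's
#' Bonferroni-based step-down under independence.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))  # 0.0199, 0.04
#' @export
holm_sidak_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  p_sorted <- p[ord]
  adj <- 1 - (1 - p_sorted)^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Site-wise ANOVA with Holm-Sidak pairwise comparisons
#'
#' One-way ANOVA of TEWL across the four measurement sites (each
#' measurement-day panel contributing one value per site), followed by
#' pairwise comparisons using t-tests with the pooled ANOVA error variance
#' and step-down Sidak adjustment ([holm_sidak_adjust()]). Repeated
#' measurements from the same patient are treated as independent
#' observations.
#'
#' @param panels Data frame with the four site columns `tewl_forehead`,
#'   `tewl_upper_limb`, `tewl_lower_limb`, `tewl_trunk`; at least 3 rows.
#' @param pairs Optional list of length-2 character vectors naming the site
#'   pairs to compare (site names without the `tewl_` prefix). Default: all
#'   6 pairs.
#' @return A list with `anova` (one-row tibble: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`) and `pairwise` (tibble: `site_a`, `site_b`,
#'   `mean_a`, `mean_b`, `p_raw`, `p_adjusted`).
#' @export
site_anova_holm_sidak <- function(panels, pairs = NULL) {
  site_cols <- c("tewl_forehead", "tewl_upper_limb", "tewl_lower_limb",
                 "tewl_trunk")
  have <- intersect(site_cols, names(panels))
  if (length(have) < 2) {
    stop("need at least 2 site columns with data", call. = FALSE)
  }
  if (nrow(panels) < 3) stop("need at least 3 panels", call. = FALSE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(panels)[, have],
    cols = dplyr::everything(),
    names_to = "site", values_to = "tewl"
  )
  long$site <- sub("^tewl_", "", long$site)
  long <- dplyr::filter(long, !is.na(.data$tewl))
  fit <- stats::aov(tewl ~ site, data = long)
  av <- summary(fit)[[1]]
  mse <- av["Residuals", "Mean Sq"]
  df_err <- av["Residuals", "Df"]
  sites <- unique(long$site)
  if (is.null(pairs)) {
    pairs <- utils::combn(sites, 2, simplify = FALSE)
  }
  means <- tapply(long$tewl, long$site, mean)
  ns <- tapply(long$tewl, long$site, length)
  pw <- purrr::map_dfr(pairs, function(pr) {
    stopifnot(all(pr %in% sites))
    se <- sqrt(mse * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tval <- (means[[pr[1]]] - means[[pr[2]]]) / se
    tibble::tibble(
      site_a = pr[1], site_b = pr[2],
      mean_a = means[[pr[1]]], mean_b = means[[pr[2]]],
      p_raw = 2 * stats::pt(-abs(tval), df_err)
    )
  })
  pw$p_adjusted <- holm_sidak_adjust(pw$p_raw)
  list(
    anova = tibble::tibble(
      f_statistic = av["site", "F value"],
      df_between = av["site", "Df"], df_within = df_err,
      p_value = av["site", "Pr(>F)"]
    ),
    pairwise = pw
  )
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x`, reporting slope, intercept,
#' R-squared, the two-sided p-value for the slope, and n. A thin, typed
#' wrapper around [stats::lm()] so downstream stages and tidiers have a
#' stable result shape.
#'
#' @param x,y Numeric vectors of equal length, n >= 3 complete pairs; `x`
#'   must not be constant.
#' @return An object of class `tewl_regression`: a list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, the underlying `lm` fit, and
#'   a `data` tibble. Methods: [print()], [generics::tidy()],
#'   [generics::glance()], [ggplot2::autoplot()].
#' @examples
#' fit_regression(1:10, 2 * (1:10) + 1)
#' @export
fit_regression <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant; slope undefined",
                              call. = FALSE)
  d <- tibble::tibble(x = x, y = y)
  fit <- stats::lm(y ~ x, data = d)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[["x"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
      n = length(x),
      fit = fit,
      data = d
    ),
    class = "tewl_regression"
  )
}

#' @export
print.tewl_regression <- function(x, ...) {
  cat("Simple linear regression (n =", x$n, ")\n")
  cat(sprintf("  slope     %10.4f  (p = %.4g)\n", x$slope, x$p_value))
  cat(sprintf("  intercept %10.4f\n", x$intercept))
  cat(sprintf("  R-squared %10.4f\n", x$r_squared))
  invisible(x)
}

#' Percent-of-mean normalization within patients
#'
#' Expresses each repeated measurement as a percentage of that patient's own
#' mean, \eqn{100\, v / \bar v_{patient}}, removing between-patient level
#' differences so that within-patient covariation can be pooled across a
#' cohort. By construction each patient's normalized values average exactly
#' 100; a patient contributing a single value yields the uninformative 100.
#'
#' @param data Data frame with one row per measurement.
#' @param value Column to normalize (tidy-evaluated).
#' @param id Patient identifier column (default `patient_id`).
#' @param suffix Suffix of the new column name (default `"_pct"`).
#' @return `data` with an added column `<value><suffix>`; rows with missing
#'   values get `NA`. Errors if any patient's mean of the non-missing
#'   values is 0.
#' @examples
#' d <- data.frame(patient_id = c("a", "a"), tewl = c(8, 12))
#' normalize_to_patient_mean(d, tewl)
#' @export
normalize_to_patient_mean <- function(data, value, id = patient_id,
                                      suffix = "_pct") {
  value <- rlang::enquo(value)
  id <- rlang::enquo(id)
  new_name <- paste0(rlang::as_name(value), suffix)
  out <- data |>
    dplyr::group_by(!!id) |>
    dplyr::mutate(
      .patient_mean = mean(!!value, na.rm = TRUE),
      !!new_name := 100 * (!!value) / .data$.patient_mean
    ) |>
    dplyr::ungroup()
  bad <- out$.patient_mean == 0 & !is.na(out$.patient_mean)
  if (any(bad)) {
    stop("patient mean of `", rlang::as_name(value),
         "` is zero for patient(s): ",
         paste(unique(dplyr::pull(out, !!id)[bad]), collapse = ", "),
         call. = FALSE)
  }
  dplyr::select(out, -".patient_mean")
}

#' Regression of formula-vs-TEWL deviation on the TEWL-based loss
#'
#' Fits the relative deviation of the formula estimate from the TEWL
#' measurement against the TEWL-based 24-h loss, the diagnostic for
#' level-dependent bias of the estimation formula (overestimation at low
#' measured loss, underestimation at high).
#'
#' @param estimates Output of [estimate_daily_loss()]; rows with
#'   `tewl_ml_per_24h <= 0` or missing deviation are dropped.
#' @return A `tewl_regression` of `relative_deviation_pct` on
#'   `tewl_ml_per_24h`.
#' @export
deviation_regression <- function(estimates) {
  d <- dplyr::filter(estimates, .data$tewl_ml_per_24h > 0,
                     !is.na(.data$relative_deviation_pct))
  if (nrow(d) < 3) stop("need at least 3 estimates with positive TEWL loss",
                        call. = FALSE)
  fit_regression(d$tewl_ml_per_24h, d$relative_deviation_pct)
}

#' Within-patient normalized TEWL--SVRI regression
#'
#' The vascular-tone analysis: whole-body weighted TEWL and SVRI are each
#' expressed as percent of the patient's own mean
#' ([normalize_to_patient_mean()]), and normalized TEWL is regressed on
#' normalized SVRI across all patient-days with an SVRI measurement. A
#' negative slope means days of lower vascular tone (vasodilation) are days
#' of higher skin water loss within the same patient. Patients without SVRI
#' are dropped; patients contributing a single pair yield the uninformative
#' point (100, 100) and can be excluded via `include_singletons = FALSE`.
#'
#' @param records Measurement table with the four site TEWL columns and
#'   `svri`.
#' @param absolute Fit on the raw (non-normalized) scales instead. Default
#'   `FALSE`.
#' @param include_singletons Keep patients with a single SVRI pair. Default
#'   `TRUE`.
#' @param renormalize Passed to [rule_of_nines_tewl()].
#' @return A `tewl_regression` (y = TEWL on x = SVRI, normalized unless
#'   `absolute`), with extra fields `n_patients` and `scale`
#'   (`"percent_of_patient_mean"` or `"absolute"`).
#' @export
tewl_svri_regression <- function(records, absolute = FALSE,
                                 include_singletons = TRUE,
                                 renormalize = FALSE) {
  d <- records |>
    dplyr::filter(!is.na(.data$svri)) |>
    dplyr::mutate(whole_body_tewl = rule_of_nines_tewl(
      .data$tewl_forehead, .data$tewl_upper_limb, .data$tewl_lower_limb,
      .data$tewl_trunk, renormalize = renormalize
    ))
  if (nrow(d) == 0) stop("no records with SVRI available", call. = FALSE)
  if (!include_singletons) {
    d <- d |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::filter(dplyr::n() > 1) |>
      dplyr::ungroup()
  }
  if (absolute) {
    fit <- fit_regression(d$svri, d$whole_body_tewl)
    fit$scale <- "absolute"
  } else {
    d <- d |>
      normalize_to_patient_mean(whole_body_tewl) |>
      normalize_to_patient_mean(svri)
    fit <- fit_regression(d$svri_pct, d$whole_body_tewl_pct)
    fit$scale <- "percent_of_patient_mean"
  }
  fit$n_patients <- dplyr::n_distinct(d$patient_id)
  fit
}
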