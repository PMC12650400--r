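#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of a simple regression fit
#'
#' @param object A `tewl_regression` from [fit_regression()].
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot: the fitted points with the least-squares line and an
#'   annotation of R^2 and p.
#' @method autoplot tewl_regression
#' @export
autoplot.tewl_regression <- function(object, xlab = "x", ylab = "y", ...) {
  lab <- sprintf("R² = %.2f, p = %.3g", object$r_squared,
                 object$p_value)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab, subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Site-wise TEWL distribution plot
#'
#' One box (with jittered points) per measurement site, the visual
#' companion of [site_anova_holm_sidak()].
#'
#' @param records Measurement table with the four `tewl_*` site columns.
#' @return A ggplot.
#' @export
plot_site_tewl <- function(records) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(records)[, c("tewl_forehead", "tewl_upper_limb",
                                   "tewl_lower_limb", "tewl_trunk")],
    cols = dplyr::everything(),
    names_to = "site", values_to = "tewl"
  )
  long$site <- factor(sub("^tewl_", "", long$site),
                      levels = c("upper_limb", "lower_limb", "trunk",
                                 "forehead"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$tewl)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "TEWL (g/h/m²)") +
    ggplot2::theme_minimal()
}

#' Paired comparison plot of the two skin-loss estimators
#'
#' Formula-based versus TEWL-based 24-h loss per record, with the identity
#' line; points above the line are records where the formula overestimates.
#'
#' @param estimates Output of [estimate_daily_loss()].
#' @return A ggplot.
#' @export
plot_method_comparison <- function(estimates) {
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$tewl_ml_per_24h,
                               y = .data$formula_ml_per_24h,
                               colour = .data$shock_type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "TEWL-based loss (mL/24 h)",
                  y = "Formula-based loss (mL/24 h)",
                  colour = "shock type") +
    ggplot2::theme_minimal()
}

#' Deviation-vs-level plot for the estimation formula
#'
#' Relative deviation of the formula from the TEWL measurement against the
#' TEWL-based loss, with the fitted line from [deviation_regression()] —
#' the level-dependent-bias diagnostic.
#'
#' @param estimates Output of [estimate_daily_loss()].
#' @return A ggplot.
#' @export
plot_deviation <- function(estimates) {
  fit <- deviation_regression(estimates)
  d <- dplyr::filter(estimates, .data$tewl_ml_per_24h > 0,
                     !is.na(.data$relative_deviation_pct))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tewl_ml_per_24h,
                                  y = .data$relative_deviation_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "TEWL-based loss (mL/24 h)",
                  y = "Deviation of formula from TEWL (%)",
                  subtitle = sprintf("R² = %.2f, p = %.3g",
                                     fit$r_squared, fit$p_value)) +
    ggplot2::theme_minimal()
}

#' Normalized TEWL--SVRI coupling plot
#'
#' Percent-of-patient-mean whole-body TEWL against percent-of-patient-mean
#' SVRI with the pooled regression line — the within-patient vascular-tone
#' association.
#'
#' @param records Measurement table with site TEWL columns and `svri`.
#' @param ... Passed to [tewl_svri_regression()].
#' @return A ggplot.
#' @export
plot_normalized_coupling <- function(records, ...) {
  fit <- tewl_svri_regression(records, absolute = FALSE, ...)
  autoplot(fit,
           xlab = "SVRI (% of patient mean)",
           ylab = "Whole-body TEWL (% of patient mean)")
}
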