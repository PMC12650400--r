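#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simple regression fit
#'
#' @param x A `tewl_regression` from [fit_regression()].
#' @param ... Unused.
#' @return A two-row tibble with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy tewl_regression
#' @export
tidy.tewl_regression <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"])
  )
}

#' One-row summary of a simple regression fit
#'
#' @param x A `tewl_regression` from [fit_regression()].
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`, `p.value`,
#'   `n` (plus `scale` and `n_patients` for TEWL--SVRI fits).
#' @method glance tewl_regression
#' @export
glance.tewl_regression <- function(x, ...) {
  out <- tibble::tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    p.value = x$p_value, n = x$n
  )
  if (!is.null(x$scale)) out$scale <- x$scale
  if (!is.null(x$n_patients)) out$n_patients <- x$n_patients
  out
}

#' Tidy a two-group comparison
#'
#' @param x A `tewl_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A two-row tibble with one row per group (`group`, `mean`, `sd`,
#'   `n`) carrying the shared `test_used` and `p.value`.
#' @method tidy tewl_group_comparison
#' @export
tidy.tewl_group_comparison <- function(x, ...) {
  tibble::tibble(
    group = c("a", "b"),
    mean = c(x$mean_a, x$mean_b),
    sd = c(x$sd_a, x$sd_b),
    n = c(x$n_a, x$n_b),
    test_used = x$test_used,
    p.value = x$p_value
  )
}
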