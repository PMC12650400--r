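# Wallace rule-of-nines surface fractions for the four measured sites.
# Both lower limbs 2 x 18 %, both upper limbs 2 x 9 %, head 9 %, trunk 36 %;
# the 1 % perineum is omitted, so the weights deliberately sum to 0.99.
.NINES_WEIGHTS <- c(forehead = 0.09, upper_limb = 0.18,
                    lower_limb = 0.36, trunk = 0.36)

.SITE_COLS <- c("tewl_forehead", "tewl_upper_limb", "tewl_lower_limb",
                "tewl_trunk")

#' Body surface area from weight and height
#'
#' Du Bois--Du Bois formula by default,
#' \eqn{BSA = 0.007184\, W^{0.425} H^{0.725}} with weight in kg and height in
#' cm; the Mosteller formula \eqn{\sqrt{WH/3600}} is selectable.
#'
#' @param weight_kg Body weight in kg (> 0).
#' @param height_cm Body height in cm (> 0).
#' @param method `"dubois"` (default) or `"mosteller"`.
#' @return Body surface area in m^2 (vectorised).
#' @examples
#' bsa(70, 170)               # ~1.81 m^2
#' bsa(70, 170, "mosteller")
#' @export
bsa <- function(weight_kg, height_cm, method = c("dubois", "mosteller")) {
  method <- match.arg(method)
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("`weight_kg` must be positive", call. = FALSE)
  }
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("`height_cm` must be positive", call. = FALSE)
  }
  switch(method,
    dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
    mosteller = sqrt(weight_kg * height_cm / 3600)
  )
}

#' Cox estimate of 24-h insensible water loss
#'
#' The bedside estimation formula: a base of 10 mL per kg body weight per
#' 24 h, corrected by 20 % per degree Celsius of core-temperature deviation
#' from 37 degrees C, and reduced by 40 % for patients mechanically ventilated
#' with active humidification (whose respiratory losses are taken as zero, so
#' the remainder is cutaneous). The temperature correction is multiplicative
#' on the base and commutes with the ventilation reduction, which is why the
#' ventilated rate is equivalently quoted as 6 mL/kg/24 h. Sub-37 temperatures
#' reduce the estimate symmetrically; the result is floored at 0.
#'
#' @param weight_kg Body weight in kg (> 0).
#' @param core_temp_c Core temperature in degrees Celsius.
#' @param ventilated Logical; mechanically ventilated with active
#'   humidification.
#' @return Estimated insensible (cutaneous) water loss in mL per 24 h
#'   (vectorised).
#' @examples
#' cox_insensible_loss(70, 37, ventilated = TRUE)   # 420
#' cox_insensible_loss(70, 38, ventilated = TRUE)   # 504
#' cox_insensible_loss(70, 37, ventilated = FALSE)  # 700
#' @export
cox_insensible_loss <- function(weight_kg, core_temp_c, ventilated) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop("`weight_kg` must be positive", call. = FALSE)
  }
  stopifnot(is.logical(ventilated) | ventilated %in% c(0, 1))
  base <- 10 * weight_kg
  corrected <- base * (1 + 0.2 * (core_temp_c - 37))
  out <- ifelse(as.logical(ventilated), corrected * 0.6, corrected)
  pmax(out, 0)
}

#' Rule-of-nines weighted whole-body TEWL
#'
#' Collapses the four site measurements (forehead, upper limb, lower limb,
#' trunk, each in g/h/m^2) into a single body-surface-weighted TEWL using the
#' Wallace rule-of-nines fractions: lower limbs 0.18 x 2, upper limbs
#' 0.09 x 2, head 0.09, trunk 0.36. The weights sum to 0.99 because the 1 %
#' perineum has no measurement site; by default they are NOT renormalized,
#' matching the clinical extrapolation as published. Set
#' `renormalize = TRUE` to divide by 0.99.
#'
#' @param forehead,upper_limb,lower_limb,trunk Site TEWL values in g/h/m^2
#'   (each >= 0; vectorised in parallel).
#' @param renormalize Divide the weighted sum by 0.99 so the weights sum to
#'   one. Default `FALSE`.
#' @return Weighted whole-body TEWL in g/h/m^2.
#' @examples
#' rule_of_nines_tewl(10, 10, 10, 10)  # 9.9
#' @export
rule_of_nines_tewl <- function(forehead, upper_limb, lower_limb, trunk,
                               renormalize = FALSE) {
  vals <- cbind(forehead, upper_limb, lower_limb, trunk)
  if (any(vals < 0, na.rm = TRUE)) {
    stop("site TEWL values must be >= 0", call. = FALSE)
  }
  out <- .NINES_WEIGHTS[["forehead"]] * forehead +
    .NINES_WEIGHTS[["upper_limb"]] * upper_limb +
    .NINES_WEIGHTS[["lower_limb"]] * lower_limb +
    .NINES_WEIGHTS[["trunk"]] * trunk
  if (renormalize) out <- out / sum(.NINES_WEIGHTS)
  out
}

#' Rule-of-nines site weights
#'
#' @param renormalize Divide by the 0.99 total. Default `FALSE`.
#' @return Named numeric vector of surface fractions for forehead, upper
#'   limb, lower limb and trunk.
#' @export
rule_of_nines_weights <- function(renormalize = FALSE) {
  w <- .NINES_WEIGHTS
  if (renormalize) w <- w / sum(w)
  w
}

#' TEWL-based 24-h skin water loss
#'
#' Extrapolates the rule-of-nines weighted TEWL (g/h/m^2) to a 24-h
#' whole-body loss: weighted TEWL x 24 h x body surface area, with grams of
#' water converted to mL at density 1 g/mL.
#'
#' @inheritParams rule_of_nines_tewl
#' @inheritParams bsa
#' @param bsa_method BSA formula, see [bsa()].
#' @return 24-h skin water loss in mL (vectorised).
#' @examples
#' tewl_daily_loss(10, 10, 10, 10, weight_kg = 70, height_cm = 170)
#' @export
tewl_daily_loss <- function(forehead, upper_limb, lower_limb, trunk,
                            weight_kg, height_cm,
                            bsa_method = c("dubois", "mosteller"),
                            renormalize = FALSE) {
  bsa_method <- match.arg(bsa_method)
  wtewl <- rule_of_nines_tewl(forehead, upper_limb, lower_limb, trunk,
                              renormalize = renormalize)
  wtewl * 24 * bsa(weight_kg, height_cm, method = bsa_method)
}

#' Relative deviation of the formula estimate from the TEWL estimate
#'
#' \eqn{100 (formula - tewl) / tewl}, in percent. Positive values mean the
#' formula overestimates relative to the measurement.
#'
#' @param formula_ml Formula-based loss in mL/24 h.
#' @param tewl_ml TEWL-based loss in mL/24 h; must be > 0.
#' @return Relative deviation in percent (vectorised).
#' @export
relative_deviation <- function(formula_ml, tewl_ml) {
  if (any(tewl_ml <= 0, na.rm = TRUE)) {
    stop("relative deviation is undefined for `tewl_ml` <= 0", call. = FALSE)
  }
  100 * (formula_ml - tewl_ml) / tewl_ml
}

#' Paired 24-h skin-loss estimates for a measurement table
#'
#' The per-record estimator stage: for each patient-day row it computes the
#' formula-based loss ([cox_insensible_loss()]), the TEWL-based loss
#' ([tewl_daily_loss()]), the body surface area, and the relative deviation
#' of the formula from the measurement. Rows with any missing site TEWL are
#' excluded from the output (no imputation across only four sites) with a
#' message; missing anthropometrics likewise.
#'
#' @param records A measurement table as returned by [read_measurements()] or
#'   [generate_cohort()]: one row per patient-day with columns `patient_id`,
#'   `shock_type`, `day`, the four `tewl_*` site columns, `weight_kg`,
#'   `height_cm`, `core_temp_c`, `ventilated`.
#' @inheritParams tewl_daily_loss
#' @return A tibble with the identifying columns plus `bsa_m2`,
#'   `weighted_tewl_g_h_m2`, `tewl_ml_per_24h`, `formula_ml_per_24h`, and
#'   `relative_deviation_pct` (`NA` when the TEWL-based loss is 0).
#' @export
estimate_daily_loss <- function(records,
                                bsa_method = c("dubois", "mosteller"),
                                renormalize = FALSE) {
  bsa_method <- match.arg(bsa_method)
  needed <- c("patient_id", "shock_type", "day", .SITE_COLS,
              "weight_kg", "height_cm", "core_temp_c", "ventilated")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("`records` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  complete <- stats::complete.cases(
    records[, c(.SITE_COLS, "weight_kg", "height_cm", "core_temp_c",
                "ventilated")]
  )
  if (any(!complete)) {
    message(sum(!complete),
            " record(s) with missing site TEWL or anthropometrics excluded",
            " from loss estimation")
  }
  rec <- dplyr::filter(tibble::as_tibble(records), complete)
  dplyr::mutate(
    rec,
    bsa_m2 = bsa(.data$weight_kg, .data$height_cm, method = bsa_method),
    weighted_tewl_g_h_m2 = rule_of_nines_tewl(
      .data$tewl_forehead, .data$tewl_upper_limb,
      .data$tewl_lower_limb, .data$tewl_trunk, renormalize = renormalize
    ),
    tewl_ml_per_24h = .data$weighted_tewl_g_h_m2 * 24 * .data$bsa_m2,
    formula_ml_per_24h = cox_insensible_loss(
      .data$weight_kg, .data$core_temp_c, .data$ventilated
    ),
    relative_deviation_pct = dplyr::if_else(
      .data$tewl_ml_per_24h > 0,
      100 * (.data$formula_ml_per_24h - .data$tewl_ml_per_24h) /
        .data$tewl_ml_per_24h,
      NA_real_
    )
  )
}
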