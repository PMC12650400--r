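.FLUID_COLS <- c("parenteral_ml", "enteral_ml", "urine_ml",
                 "ultrafiltrate_ml")

#' 24-h fluid intake
#'
#' Parenteral plus enteral volume for one or more patient-days.
#'
#' @param parenteral_ml,enteral_ml Volumes in mL (>= 0, vectorised).
#' @return Total intake in mL.
#' @export
total_intake <- function(parenteral_ml, enteral_ml) {
  if (any(c(parenteral_ml, enteral_ml) < 0, na.rm = TRUE)) {
    stop("fluid volumes must be >= 0", call. = FALSE)
  }
  parenteral_ml + enteral_ml
}

#' 24-h fluid output under a chosen skin-loss estimate
#'
#' Urine plus ultrafiltrate plus the 24-h skin water loss (from either
#' estimator) plus any other measured output.
#'
#' @param urine_ml,ultrafiltrate_ml Measured outputs in mL (>= 0).
#' @param skin_loss_ml Estimated 24-h skin water loss in mL (>= 0).
#' @param other_output_ml Additional measured output (drains, stool), mL;
#'   defaults to 0.
#' @return Total output in mL (vectorised).
#' @export
total_output <- function(urine_ml, ultrafiltrate_ml, skin_loss_ml,
                         other_output_ml = 0) {
  if (any(skin_loss_ml < 0, na.rm = TRUE)) {
    stop("`skin_loss_ml` must be >= 0", call. = FALSE)
  }
  if (any(c(urine_ml, ultrafiltrate_ml, other_output_ml) < 0, na.rm = TRUE)) {
    stop("fluid volumes must be >= 0", call. = FALSE)
  }
  urine_ml + ultrafiltrate_ml + skin_loss_ml + other_output_ml
}

#' Single-day fluid balance
#'
#' Intake minus output; positive values mean net fluid gain.
#'
#' @inheritParams total_intake
#' @inheritParams total_output
#' @param skin_loss_method Label recorded with the result, `"formula"` or
#'   `"tewl"`.
#' @return A tibble with `total_intake_ml`, `total_output_ml`, `balance_ml`,
#'   and `skin_loss_method`.
#' @examples
#' daily_balance(4581, 136.6, 840.7, 425.8, skin_loss_ml = 383.6,
#'               skin_loss_method = "tewl")
#' @export
daily_balance <- function(parenteral_ml, enteral_ml, urine_ml,
                          ultrafiltrate_ml, skin_loss_ml,
                          other_output_ml = 0,
                          skin_loss_method = c("formula", "tewl")) {
  skin_loss_method <- match.arg(skin_loss_method)
  intake <- total_intake(parenteral_ml, enteral_ml)
  output <- total_output(urine_ml, ultrafiltrate_ml, skin_loss_ml,
                         other_output_ml)
  tibble::tibble(
    total_intake_ml = intake,
    total_output_ml = output,
    balance_ml = intake - output,
    skin_loss_method = skin_loss_method
  )
}

#' Per-record fluid-balance table under one or both skin-loss methods
#'
#' Joins the loss estimates from [estimate_daily_loss()] back to the fluid
#' ledger and emits one row per record and skin-loss method. Records with any
#' missing fluid field are skipped (missing is absent data, never zero) with
#' a message.
#'
#' @param records Measurement table (see [read_measurements()]); must contain
#'   the fluid columns `parenteral_ml`, `enteral_ml`, `urine_ml`,
#'   `ultrafiltrate_ml` and optionally `other_output_ml`.
#' @param estimates Output of [estimate_daily_loss()] on the same records; if
#'   `NULL` it is computed here.
#' @param methods Character subset of `c("formula", "tewl")`.
#' @param ... Passed on to [estimate_daily_loss()] when `estimates` is NULL.
#' @return A tibble with one row per record x method: identifying columns,
#'   `skin_loss_method`, `skin_loss_ml`, `total_intake_ml`,
#'   `total_output_ml`, `balance_ml`.
#' @export
balance_table <- function(records, estimates = NULL,
                          methods = c("formula", "tewl"), ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  missing_cols <- setdiff(.FLUID_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("`records` is missing fluid column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(estimates)) estimates <- estimate_daily_loss(records, ...)
  if (!"other_output_ml" %in% names(records)) {
    records$other_output_ml <- 0
  }
  fluid_ok <- stats::complete.cases(records[, .FLUID_COLS])
  if (any(!fluid_ok)) {
    message(sum(!fluid_ok),
            " record(s) with missing fluid fields skipped in balance table")
  }
  led <- dplyr::inner_join(
    dplyr::filter(
      records[, c("patient_id", "shock_type", "day", .FLUID_COLS,
                  "other_output_ml")],
      fluid_ok
    ),
    estimates[, c("patient_id", "day", "formula_ml_per_24h",
                  "tewl_ml_per_24h")],
    by = c("patient_id", "day")
  )
  led <- tidyr::pivot_longer(
    led,
    cols = c("formula_ml_per_24h", "tewl_ml_per_24h"),
    names_to = "skin_loss_method", values_to = "skin_loss_ml"
  )
  led$skin_loss_method <- ifelse(
    led$skin_loss_method == "formula_ml_per_24h", "formula", "tewl"
  )
  led <- dplyr::filter(led, .data$skin_loss_method %in% methods)
  dplyr::mutate(
    led,
    total_intake_ml = total_intake(.data$parenteral_ml, .data$enteral_ml),
    total_output_ml = total_output(.data$urine_ml, .data$ultrafiltrate_ml,
                                   .data$skin_loss_ml,
                                   .data$other_output_ml),
    balance_ml = .data$total_intake_ml - .data$total_output_ml
  )
}

#' Group summary of the fluid ledger, mean +/- SD by shock type
#'
#' Summarises each ledger quantity (intakes, outputs, skin losses, balances)
#' as mean and SD per shock type, together with the two-group comparison
#' chosen by the normality gate of [compare_groups()] — the layout of a
#' cohort fluid table.
#'
#' @param balances Output of [balance_table()] with both methods present.
#' @param records The measurement table the balances came from.
#' @param normality_alpha Alpha for the normality gate (see
#'   [compare_groups()]).
#' @return A tibble with one row per ledger quantity: `variable`,
#'   `mean_septic`, `sd_septic`, `n_septic`, `mean_cardiogenic`,
#'   `sd_cardiogenic`, `n_cardiogenic`, `test_used`, `p_value`.
#' @export
balance_summary <- function(balances, records, normality_alpha = 0.05) {
  long <- dplyr::bind_rows(
    records |>
      dplyr::select(dplyr::all_of(c("patient_id", "shock_type", "day",
                                    .FLUID_COLS))) |>
      dplyr::mutate(total_intake_ml = total_intake(.data$parenteral_ml,
                                                   .data$enteral_ml)) |>
      tidyr::pivot_longer(cols = c(dplyr::all_of(.FLUID_COLS),
                                   "total_intake_ml"),
                          names_to = "variable", values_to = "value"),
    balances |>
      dplyr::mutate(
        skin = paste0("skin_loss_", .data$skin_loss_method, "_ml"),
        outp = paste0("total_output_", .data$skin_loss_method, "_ml"),
        bal = paste0("balance_", .data$skin_loss_method, "_ml")
      ) |>
      (\(d) dplyr::bind_rows(
        dplyr::transmute(d, .data$patient_id, .data$shock_type, .data$day,
                         variable = .data$skin, value = .data$skin_loss_ml),
        dplyr::transmute(d, .data$patient_id, .data$shock_type, .data$day,
                         variable = .data$outp, value = .data$total_output_ml),
        dplyr::transmute(d, .data$patient_id, .data$shock_type, .data$day,
                         variable = .data$bal, value = .data$balance_ml)
      ))()
  )
  order_vars <- c("parenteral_ml", "enteral_ml", "total_intake_ml",
                  "urine_ml", "ultrafiltrate_ml",
                  "skin_loss_formula_ml", "skin_loss_tewl_ml",
                  "total_output_formula_ml", "total_output_tewl_ml",
                  "balance_formula_ml", "balance_tewl_ml")
  vars <- intersect(order_vars, unique(long$variable))
  purrr::map_dfr(vars, function(v) {
    d <- dplyr::filter(long, .data$variable == v, !is.na(.data$value))
    a <- d$value[d$shock_type == "septic"]
    b <- d$value[d$shock_type == "cardiogenic"]
    cmp <- if (length(a) >= 2 && length(b) >= 2) {
      compare_groups(a, b, alpha = normality_alpha)
    } else {
      tibble::tibble(test_used = NA_character_, p_value = NA_real_)
    }
    tibble::tibble(
      variable = v,
      mean_septic = mean(a), sd_septic = stats::sd(a),
      n_septic = length(a),
      mean_cardiogenic = mean(b), sd_cardiogenic = stats::sd(b),
      n_cardiogenic = length(b),
      test_used = cmp$test_used, p_value = cmp$p_value
    )
  })
}
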