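.MANDATORY_COLS <- c("patient_id", "shock_type", "day", "tewl_forehead",
                     "tewl_upper_limb", "tewl_lower_limb", "tewl_trunk",
                     "weight_kg", "height_cm", "core_temp_c", "ventilated",
                     "parenteral_ml", "enteral_ml", "urine_ml",
                     "ultrafiltrate_ml")

#' Read a measurement table
#'
#' Reads a per-patient-day CSV in the canonical schema (UTF-8, header, dot
#' decimal separator): `patient_id`, `shock_type` (septic|cardiogenic),
#' `day`, the four site TEWL columns `tewl_forehead`, `tewl_upper_limb`,
#' `tewl_lower_limb`, `tewl_trunk` (g/h/m^2), `weight_kg`, `height_cm`,
#' `core_temp_c`, `ventilated` (logical), `svri` (optional; may be missing
#' for patients without invasive monitoring), `parenteral_ml`,
#' `enteral_ml`, `urine_ml`, `ultrafiltrate_ml`, and optionally
#' `other_output_ml`. Lines starting with `#` are ignored.
#'
#' Rows violating the record invariants (non-positive weight or height,
#' core temperature outside 30--45 deg C, day < 1, negative TEWL or fluid
#' volume, unknown shock type) are rejected with a row-numbered warning;
#' the remaining rows load.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated records; the rejected rows (with a
#'   `reason` column) are attached as attribute `"rejected"`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0) stop("empty measurement file: ", path, call. = FALSE)
  missing_cols <- setdiff(.MANDATORY_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("measurement file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"svri" %in% names(raw)) raw$svri <- NA_real_
  raw$ventilated <- as.logical(raw$ventilated)
  validate_measurements(raw)
}

#' Validate a measurement table
#'
#' Applies the record invariants row by row; see [read_measurements()] for
#' the rules. Usable directly on in-memory data frames.
#'
#' @param records Data frame in the measurement schema.
#' @return The valid rows as a tibble, with rejected rows (and a `reason`
#'   column) in attribute `"rejected"`; warns when any row is dropped.
#' @export
validate_measurements <- function(records) {
  records <- tibble::as_tibble(records)
  reason <- rep(NA_character_, nrow(records))
  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  site_cols <- c("tewl_forehead", "tewl_upper_limb", "tewl_lower_limb",
                 "tewl_trunk")
  fluid_cols <- c("parenteral_ml", "enteral_ml", "urine_ml",
                  "ultrafiltrate_ml")
  flag(!records$shock_type %in% c("septic", "cardiogenic"),
       "unknown shock_type")
  flag(!is.na(records$day) & records$day < 1, "day < 1")
  flag(!is.na(records$weight_kg) & records$weight_kg <= 0,
       "non-positive weight_kg")
  flag(!is.na(records$height_cm) & records$height_cm <= 0,
       "non-positive height_cm")
  flag(!is.na(records$core_temp_c) &
         (records$core_temp_c < 30 | records$core_temp_c > 45),
       "core_temp_c outside 30-45")
  for (cc in c(site_cols, fluid_cols)) {
    flag(!is.na(records[[cc]]) & records[[cc]] < 0, paste("negative", cc))
  }
  if ("svri" %in% names(records)) {
    flag(!is.na(records$svri) & records$svri <= 0, "non-positive svri")
  }
  bad <- !is.na(reason)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: ",
            paste(sprintf("row %d (%s)", which(bad), reason[bad]),
                  collapse = "; "),
            call. = FALSE)
  }
  out <- records[!bad, ]
  rejected <- records[bad, ]
  rejected$reason <- reason[bad]
  attr(out, "rejected") <- rejected
  out
}

#' Write a measurement table
#'
#' Canonical CSV writer for the measurement schema; a `write` followed by
#' [read_measurements()] round-trips losslessly to full double precision.
#'
#' @param records Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Ties the stages together over one measurement table: loss estimation
#' ([estimate_daily_loss()]), the fluid ledger ([balance_table()],
#' [balance_summary()]), the site ANOVA, the paired method comparison, the
#' method-agreement and deviation regressions, and the TEWL--SVRI
#' regressions (absolute and percent-normalized). Writes a results bundle:
#'
#' * `estimates.csv` — per-record paired loss estimates
#' * `balance.csv` — per-record x method fluid ledger
#' * `group_summary.csv` — mean +/- SD by shock type with gated tests
#' * `regressions.csv` — slope/intercept/R^2/p for each regression
#' * `report.txt` — plain-text analysis report
#' * `run_metadata.yaml` — configuration, seed, package version, run id
#'
#' The run id is a content hash of the input, so identical input and
#' configuration produce byte-identical numeric outputs. If every record
#' lacks SVRI, the TEWL--SVRI analyses are skipped with an explicit notice
#' in the report and the rest completes.
#'
#' @param input A measurement tibble, a path to a measurement CSV, or a
#'   `synthetic_cohort`.
#' @param output_dir Directory for the results bundle (created if needed).
#' @param methods Skin-loss methods to carry through the ledger.
#' @param bsa_method,renormalize Passed to [estimate_daily_loss()].
#' @param normality_alpha Alpha of the normality gate in group comparisons.
#' @param seed Recorded in the metadata (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with the in-memory results (`estimates`,
#'   `balances`, `group_summary`, `regressions`, `site_anova`,
#'   `paired_test`) and `paths` of the files written.
#' @export
run_pipeline <- function(input, output_dir,
                         methods = c("formula", "tewl"),
                         bsa_method = c("dubois", "mosteller"),
                         renormalize = FALSE, normality_alpha = 0.05,
                         seed = NULL) {
  bsa_method <- match.arg(bsa_method)
  methods <- match.arg(methods, several.ok = TRUE)
  if (inherits(input, "synthetic_cohort")) {
    records <- input$records
    input_label <- sprintf("synthetic cohort (seed %d)", input$truth$seed)
  } else if (is.character(input)) {
    records <- read_measurements(input)
    input_label <- input
  } else {
    records <- validate_measurements(input)
    input_label <- "in-memory records"
  }
  if (nrow(records) == 0) stop("no valid records to analyse", call. = FALSE)

  run_id <- .content_hash(records)

  estimates <- estimate_daily_loss(records, bsa_method = bsa_method,
                                   renormalize = renormalize)
  balances <- balance_table(records, estimates = estimates,
                            methods = methods)
  two_arms <- length(unique(records$shock_type)) == 2
  group_summary <- if (two_arms) {
    balance_summary(balances, records, normality_alpha = normality_alpha)
  } else {
    NULL
  }
  site_anova <- tryCatch(site_anova_holm_sidak(records),
                         error = function(e) NULL)
  paired <- tryCatch(
    compare_methods_paired(estimates$formula_ml_per_24h,
                           estimates$tewl_ml_per_24h),
    error = function(e) NULL
  )

  agreement <- tryCatch(
    fit_regression(estimates$tewl_ml_per_24h, estimates$formula_ml_per_24h),
    error = function(e) NULL
  )
  deviation <- tryCatch(deviation_regression(estimates),
                        error = function(e) NULL)
  have_svri <- any(!is.na(records$svri))
  svri_abs <- svri_norm <- NULL
  if (have_svri) {
    svri_abs <- tryCatch(tewl_svri_regression(records, absolute = TRUE),
                         error = function(e) NULL)
    svri_norm <- tryCatch(tewl_svri_regression(records, absolute = FALSE),
                          error = function(e) NULL)
  }
  reg_row <- function(name, fit) {
    if (is.null(fit)) return(NULL)
    tibble::tibble(analysis = name, slope = fit$slope,
                   intercept = fit$intercept, r_squared = fit$r_squared,
                   p_value = fit$p_value, n = fit$n)
  }
  regressions <- dplyr::bind_rows(
    reg_row("method_agreement", agreement),
    reg_row("deviation_vs_tewl", deviation),
    reg_row("tewl_svri_absolute", svri_abs),
    reg_row("tewl_svri_normalized", svri_norm)
  )

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    estimates = file.path(output_dir, "estimates.csv"),
    balance = file.path(output_dir, "balance.csv"),
    group_summary = file.path(output_dir, "group_summary.csv"),
    regressions = file.path(output_dir, "regressions.csv"),
    report = file.path(output_dir, "report.txt"),
    metadata = file.path(output_dir, "run_metadata.yaml")
  )
  write_with_id <- function(df, path) {
    writeLines(paste0("# run_id: ", run_id), path)
    if (!is.null(df)) {
      readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                       progress = FALSE)
    }
    path
  }
  write_with_id(estimates, paths$estimates)
  write_with_id(balances, paths$balance)
  write_with_id(group_summary, paths$group_summary)
  write_with_id(regressions, paths$regressions)

  writeLines(.render_report(run_id, input_label, records, estimates,
                            group_summary, site_anova, paired, regressions,
                            have_svri),
             paths$report)
  yaml::write_yaml(list(
    run_id = run_id,
    input = input_label,
    n_records = nrow(records),
    methods = methods,
    bsa_method = bsa_method,
    renormalize_weights = renormalize,
    normality_alpha = normality_alpha,
    seed = seed,
    package_version = as.character(utils::packageVersion("tewlbalance"))
  ), paths$metadata)

  invisible(list(
    estimates = estimates, balances = balances,
    group_summary = group_summary, regressions = regressions,
    site_anova = site_anova, paired_test = paired,
    run_id = run_id, paths = paths
  ))
}

# order-stable content hash of a data frame (first 12 hex digits of the md5
# of its CSV serialisation); used as the run id
.content_hash <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  readr::write_csv(df, tmp, progress = FALSE)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

.render_report <- function(run_id, input_label, records, estimates,
                           group_summary, site_anova, paired, regressions,
                           have_svri) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  lines <- c(
    "24-h skin water loss and fluid balance analysis",
    paste0("run id: ", run_id),
    paste0("input:  ", input_label),
    sprintf("records: %d patient-days from %d patients (%s)",
            nrow(records), dplyr::n_distinct(records$patient_id),
            paste(sprintf("%d %s", table(records$shock_type)[
              unique(records$shock_type)], unique(records$shock_type)),
              collapse = ", ")),
    ""
  )
  if (!is.null(paired)) {
    lines <- c(lines, "Paired method comparison (Wilcoxon signed-rank):",
               sprintf(paste0("  formula median %.1f mL vs TEWL median",
                              " %.1f mL, n = %d, p = %s"),
                       paired$median_formula, paired$median_tewl,
                       paired$n_pairs, fmt_p(paired$p_value)),
               "")
  }
  if (!is.null(site_anova)) {
    lines <- c(lines, "Site-wise one-way ANOVA:",
               sprintf("  F(%d, %d) = %.2f, p = %s",
                       site_anova$anova$df_between,
                       site_anova$anova$df_within,
                       site_anova$anova$f_statistic,
                       fmt_p(site_anova$anova$p_value)),
               "  Holm-Sidak pairwise comparisons:",
               sprintf("    %s vs %s: %.2f vs %.2f g/h/m2, adj. p = %s",
                       site_anova$pairwise$site_a,
                       site_anova$pairwise$site_b,
                       site_anova$pairwise$mean_a,
                       site_anova$pairwise$mean_b,
                       fmt_p(site_anova$pairwise$p_adjusted)),
               "")
  }
  if (!is.null(group_summary)) {
    lines <- c(lines, "Group summary (mean +/- SD, septic vs cardiogenic):",
               sprintf("  %-26s %9.1f +/- %8.1f | %9.1f +/- %8.1f  [%s, p = %s]",
                       group_summary$variable,
                       group_summary$mean_septic, group_summary$sd_septic,
                       group_summary$mean_cardiogenic,
                       group_summary$sd_cardiogenic,
                       group_summary$test_used,
                       fmt_p(group_summary$p_value)),
               "")
  }
  if (nrow(regressions) > 0) {
    lines <- c(lines, "Regressions:",
               sprintf("  %-22s slope %9.3f, R2 = %.3f, p = %s, n = %d",
                       regressions$analysis, regressions$slope,
                       regressions$r_squared, fmt_p(regressions$p_value),
                       regressions$n),
               "")
  }
  if (!have_svri) {
    lines <- c(lines,
               "NOTE: no SVRI measurements in input; TEWL-SVRI analyses skipped.")
  }
  lines
}
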