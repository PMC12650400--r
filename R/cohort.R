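# mean/sd on the natural scale -> meanlog/sdlog of a log-normal
.lnorm_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Configuration for the synthetic ICU cohort generator
#'
#' Bundles, with validation, every knob of [generate_cohort()]. The defaults
#' emulate a small two-arm shock cohort: 5 septic and 3 cardiogenic
#' patients, 2--6 daily measurements each, log-normal site TEWL with an
#' elevated forehead, low SVRI in septic and high SVRI in cardiogenic shock,
#' shock-type differences in parenteral intake and ultrafiltrate, and a
#' negative within-patient coupling between percent-normalized whole-body
#' TEWL and percent-normalized SVRI.
#'
#' @param n_septic,n_cardiogenic Number of patients per arm (total >= 1).
#' @param days_min,days_max Range of daily measurements per patient
#'   (1 <= days_min <= days_max).
#' @param site_tewl_mean Named vector of natural-scale mean site TEWL in
#'   g/h/m^2 for `upper_limb`, `lower_limb`, `trunk` (the forehead mean is
#'   `forehead_multiplier` times the trunk mean).
#' @param site_tewl_sd Natural-scale SDs matching `site_tewl_mean`; the
#'   forehead SD scales with the multiplier so its coefficient of variation
#'   matches the trunk's.
#' @param forehead_multiplier Ratio of forehead to trunk mean TEWL (default
#'   1.553).
#' @param svri_mean_by_shock,svri_sd_by_shock Named vectors (`septic`,
#'   `cardiogenic`) of SVRI mean and day-to-day SD in dyn s cm^-5 m^2;
#'   septic low (vasodilation), cardiogenic high.
#' @param coupling_slope_beta Slope of the within-patient coupling on the
#'   percent-of-mean scale: normalized TEWL = 100 + beta (normalized SVRI -
#'   100) + noise. Default -1.
#' @param coupling_noise_sd SD of the coupling noise in percent points.
#'   Default 24, chosen so the normalized regression explains roughly half
#'   the variance at the default SVRI spread.
#' @param fluid_params Per-shock-type list of `c(mean, sd)` (mL) for
#'   `parenteral`, `enteral`, `urine`, `ultrafiltrate`.
#' @param weight_mean,weight_sd,height_mean,height_sd Anthropometrics (kg,
#'   cm), one draw per patient.
#' @param temp_mean,temp_sd Core temperature (deg C), one draw per
#'   patient-day.
#' @param svri_missing Named vector: number of patients per arm whose SVRI
#'   is withheld (no invasive monitor), mimicking real indication gaps.
#' @param day_ar1 Lag-1 autocorrelation of the latent within-patient SVRI
#'   deviations; default 0 (independent days).
#' @param seed Integer seed; every cohort drawn from the same config is
#'   identical.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_septic = 5, n_cardiogenic = 3,
                          days_min = 2, days_max = 6,
                          site_tewl_mean = c(upper_limb = 6.83,
                                             lower_limb = 6.83,
                                             trunk = 6.83),
                          site_tewl_sd = c(upper_limb = 5.92,
                                           lower_limb = 5.92,
                                           trunk = 5.92),
                          forehead_multiplier = 1.553,
                          svri_mean_by_shock = c(septic = 1400,
                                                 cardiogenic = 2800),
                          svri_sd_by_shock = c(septic = 350,
                                               cardiogenic = 700),
                          coupling_slope_beta = -1.0,
                          coupling_noise_sd = 24,
                          fluid_params = list(
                            septic = list(parenteral = c(4581, 1337),
                                          enteral = c(136.6, 268.4),
                                          urine = c(840.7, 872.7),
                                          ultrafiltrate = c(425.8, 584.7)),
                            cardiogenic = list(parenteral = c(3012, 715.1),
                                               enteral = c(353.8, 371.8),
                                               urine = c(896.9, 1176),
                                               ultrafiltrate = c(1728, 1454))
                          ),
                          weight_mean = 80, weight_sd = 15,
                          height_mean = 172, height_sd = 9,
                          temp_mean = 37.3, temp_sd = 0.8,
                          svri_missing = c(septic = 1, cardiogenic = 1),
                          day_ar1 = 0,
                          seed = 1L) {
  cfg <- list(
    n_septic = n_septic, n_cardiogenic = n_cardiogenic,
    days_min = days_min, days_max = days_max,
    site_tewl_mean = site_tewl_mean, site_tewl_sd = site_tewl_sd,
    forehead_multiplier = forehead_multiplier,
    svri_mean_by_shock = svri_mean_by_shock,
    svri_sd_by_shock = svri_sd_by_shock,
    coupling_slope_beta = coupling_slope_beta,
    coupling_noise_sd = coupling_noise_sd,
    fluid_params = fluid_params,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd,
    temp_mean = temp_mean, temp_sd = temp_sd,
    svri_missing = svri_missing, day_ar1 = day_ar1,
    seed = as.integer(seed)
  )
  .validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid cohort config: `", field, "` ", why, call. = FALSE)
  }
  if (cfg$n_septic < 0) fail("n_septic", "must be >= 0")
  if (cfg$n_cardiogenic < 0) fail("n_cardiogenic", "must be >= 0")
  if (cfg$n_septic + cfg$n_cardiogenic < 1) {
    fail("n_septic + n_cardiogenic", "must be >= 1")
  }
  if (cfg$days_min < 1) fail("days_min", "must be >= 1")
  if (cfg$days_min > cfg$days_max) fail("days_min", "must be <= days_max")
  sites <- c("upper_limb", "lower_limb", "trunk")
  if (!all(sites %in% names(cfg$site_tewl_mean))) {
    fail("site_tewl_mean", "must name upper_limb, lower_limb, trunk")
  }
  if (!all(sites %in% names(cfg$site_tewl_sd))) {
    fail("site_tewl_sd", "must name upper_limb, lower_limb, trunk")
  }
  if (any(cfg$site_tewl_mean <= 0)) fail("site_tewl_mean", "must be > 0")
  sds <- c(cfg$site_tewl_sd, cfg$svri_sd_by_shock, cfg$coupling_noise_sd,
           cfg$weight_sd, cfg$height_sd, cfg$temp_sd)
  if (any(sds < 0)) fail("(an SD field)", "must be >= 0")
  if (cfg$forehead_multiplier <= 0) {
    fail("forehead_multiplier", "must be > 0")
  }
  for (arm in c("septic", "cardiogenic")) {
    if (!arm %in% names(cfg$svri_mean_by_shock)) {
      fail("svri_mean_by_shock", paste("must name", arm))
    }
    if (!arm %in% names(cfg$fluid_params)) {
      fail("fluid_params", paste("must name", arm))
    }
    for (f in c("parenteral", "enteral", "urine", "ultrafiltrate")) {
      par <- cfg$fluid_params[[arm]][[f]]
      if (is.null(par) || length(par) != 2 || par[2] < 0) {
        fail("fluid_params", paste0("$", arm, "$", f,
                                    " must be c(mean, sd) with sd >= 0"))
      }
    }
  }
  if (abs(cfg$day_ar1) >= 1) fail("day_ar1", "must lie in (-1, 1)")
  invisible(cfg)
}

#' Generate a synthetic ICU shock cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes, so every stage is testable without patient data. Per patient: a
#' shock type, 2--6 measurement days, anthropometrics, and a log-normal base
#' panel of site TEWL values (forehead elevated over the trunk). Per
#' patient-day: a latent SVRI (arm-specific mean/SD, optionally AR(1)
#' correlated across days), percent-normalized within the patient; the
#' day's whole panel is then scaled so that percent-normalized whole-body
#' TEWL follows `100 + beta (SVRI_pct - 100) + noise`, which plants the
#' within-patient coupling at a known slope `beta`. Fluid volumes are drawn
#' per arm from the configured means/SDs. All draws are truncated at 0.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A list of class `synthetic_cohort` with elements `records` (a
#'   tibble in the measurement-table schema, see [read_measurements()]) and
#'   `truth` (the generating parameters, the seed used, and a per-patient
#'   table of base panels and latent means).
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 42))
#' dplyr::count(coh$records, shock_type)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  .validate_cohort_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  set.seed(seed)

  arms <- c(rep("septic", config$n_septic),
            rep("cardiogenic", config$n_cardiogenic))
  ids <- c(sprintf("S%02d", seq_len(config$n_septic)),
           sprintf("C%02d", seq_len(config$n_cardiogenic)))
  # which patients go unmonitored, per arm
  no_svri <- character(0)
  for (arm in c("septic", "cardiogenic")) {
    k <- min(config$svri_missing[[arm]], sum(arms == arm))
    if (k > 0) no_svri <- c(no_svri, utils::head(ids[arms == arm], k))
  }

  site_mean <- c(
    forehead = config$forehead_multiplier * config$site_tewl_mean[["trunk"]],
    config$site_tewl_mean[c("upper_limb", "lower_limb", "trunk")]
  )
  site_sd <- c(
    forehead = config$forehead_multiplier * config$site_tewl_sd[["trunk"]],
    config$site_tewl_sd[c("upper_limb", "lower_limb", "trunk")]
  )

  patients <- vector("list", length(ids))
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    arm <- arms[i]
    n_days <- sample(seq(config$days_min, config$days_max), 1)
    weight <- max(1, stats::rnorm(1, config$weight_mean, config$weight_sd))
    height <- max(50, stats::rnorm(1, config$height_mean, config$height_sd))
    base_panel <- vapply(names(site_mean), function(s) {
      lp <- .lnorm_params(site_mean[[s]], site_sd[[s]])
      stats::rlnorm(1, lp$meanlog, lp$sdlog)
    }, numeric(1))

    # latent SVRI series, optionally AR(1) across days
    z <- stats::rnorm(n_days)
    if (config$day_ar1 != 0 && n_days > 1) {
      rho <- config$day_ar1
      for (t in 2:n_days) {
        z[t] <- rho * z[t - 1] + sqrt(1 - rho^2) * z[t]
      }
    }
    svri <- pmax(0, config$svri_mean_by_shock[[arm]] +
                   config$svri_sd_by_shock[[arm]] * z)
    svri_pct <- if (mean(svri) > 0) 100 * svri / mean(svri) else rep(100, n_days)

    tewl_pct <- 100 + config$coupling_slope_beta * (svri_pct - 100) +
      stats::rnorm(n_days, 0, config$coupling_noise_sd)
    tewl_pct <- pmax(0, tewl_pct)

    fl <- config$fluid_params[[arm]]
    draw_fluid <- function(par) pmax(0, stats::rnorm(n_days, par[1], par[2]))

    records[[i]] <- tibble::tibble(
      patient_id = ids[i],
      shock_type = arm,
      day = seq_len(n_days),
      tewl_forehead = base_panel[["forehead"]] * tewl_pct / 100,
      tewl_upper_limb = base_panel[["upper_limb"]] * tewl_pct / 100,
      tewl_lower_limb = base_panel[["lower_limb"]] * tewl_pct / 100,
      tewl_trunk = base_panel[["trunk"]] * tewl_pct / 100,
      weight_kg = weight,
      height_cm = height,
      core_temp_c = stats::rnorm(n_days, config$temp_mean, config$temp_sd),
      ventilated = TRUE,
      svri = if (ids[i] %in% no_svri) NA_real_ else svri,
      parenteral_ml = draw_fluid(fl$parenteral),
      enteral_ml = draw_fluid(fl$enteral),
      urine_ml = draw_fluid(fl$urine),
      ultrafiltrate_ml = draw_fluid(fl$ultrafiltrate)
    )
    patients[[i]] <- tibble::tibble(
      patient_id = ids[i], shock_type = arm, n_days = n_days,
      weight_kg = weight, height_cm = height,
      base_forehead = base_panel[["forehead"]],
      base_upper_limb = base_panel[["upper_limb"]],
      base_lower_limb = base_panel[["lower_limb"]],
      base_trunk = base_panel[["trunk"]],
      svri_observed = !(ids[i] %in% no_svri)
    )
  }

  structure(
    list(
      records = dplyr::bind_rows(records),
      truth = list(
        seed = seed,
        coupling_slope_beta = config$coupling_slope_beta,
        coupling_noise_sd = config$coupling_noise_sd,
        config = unclass(config),
        patients = dplyr::bind_rows(patients)
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ICU cohort:",
      dplyr::n_distinct(x$records$patient_id), "patients,",
      nrow(x$records), "patient-day records",
      sprintf("(seed %d, coupling beta %.2f)\n",
              x$truth$seed, x$truth$coupling_slope_beta))
  invisible(x)
}

#' Simulate a 1-Hz evaporimeter reading stream
#'
#' Produces the instantaneous TEWL series an open-chamber probe would
#' record after placement: the reading starts offset from the true flux
#' (probe microclimate still equilibrating) and relaxes toward it
#' exponentially, with additive Gaussian sensor noise. Used to exercise the
#' stabilization stopping rule ([stabilize_tewl()]).
#'
#' @param true_tewl True steady-state TEWL in g/h/m^2.
#' @param noise_sd SD of per-second sensor noise, g/h/m^2 (>= 0).
#' @param drift_per_s Initial drift rate in g/h/m^2 per second; the starting
#'   offset is `drift_per_s * drift_tau_s` and decays as
#'   `exp(-t / drift_tau_s)`. Zero gives a drift-free stream.
#' @param duration_s Stream length in seconds (>= 1).
#' @param drift_tau_s Drift time constant in seconds (default 2: the
#'   chamber microclimate equilibrates within seconds of probe placement;
#'   the minutes-long site times of the field protocol are dominated by
#'   probe handling, not this relaxation).
#' @param seed Optional integer seed.
#' @return A tibble with columns `seconds` (1-based) and `tewl`.
#' @examples
#' s <- generate_sensor_stream(10, noise_sd = 0.05, drift_per_s = 1.0,
#'                             duration_s = 240, seed = 7)
#' stabilize_tewl(s$tewl)
#' @export
generate_sensor_stream <- function(true_tewl, noise_sd = 0.05,
                                   drift_per_s = 1.0, duration_s = 240,
                                   drift_tau_s = 2, seed = NULL) {
  if (duration_s < 1) stop("`duration_s` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(duration_s)
  offset <- drift_per_s * drift_tau_s * exp(-t / drift_tau_s)
  tibble::tibble(
    seconds = t,
    tewl = true_tewl + offset + stats::rnorm(duration_s, 0, noise_sd)
  )
}

#' Write a synthetic cohort to disk
#'
#' Writes the records as a CSV in the measurement-table schema and the
#' generating truth (seed, coupling parameters, per-patient latents) as a
#' YAML sidecar.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written (`records`, `truth`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records_path <- file.path(dir, "cohort_records.csv")
  truth_path <- file.path(dir, "cohort_truth.yaml")
  readr::write_csv(cohort$records, records_path, progress = FALSE)
  truth <- cohort$truth
  truth$patients <- as.data.frame(truth$patients)
  yaml::write_yaml(truth, truth_path)
  invisible(list(records = records_path, truth = truth_path))
}
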