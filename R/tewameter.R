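#' Saturation vapor pressure of water (Magnus form)
#'
#' Computes the saturation water-vapor pressure over a plane liquid surface
#' using the Magnus approximation
#' \deqn{e_s(T) = 6.112 \exp\!\left(\frac{17.62\,T}{243.12 + T}\right)}
#' with \eqn{T} in degrees Celsius and the result in hPa. This is the standard
#' psychrometric form used to convert relative-humidity readings into absolute
#' vapor densities.
#'
#' @param temp_c Air temperature in degrees Celsius. Must lie in the formula's
#'   validity range \eqn{[-40, 60]}.
#' @return Saturation vapor pressure in hPa (vectorised over `temp_c`).
#' @examples
#' saturation_vapor_pressure(0)   # ~6.11 hPa
#' saturation_vapor_pressure(20)  # ~23.4 hPa
#' @export
saturation_vapor_pressure <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  if (any(!is.finite(temp_c)) || any(temp_c < -40 | temp_c > 60)) {
    stop("`temp_c` must be finite and within [-40, 60] degrees C", call. = FALSE)
  }
  6.112 * exp(17.62 * temp_c / (243.12 + temp_c))
}

# specific gas constant of water vapor, J kg^-1 K^-1
.R_VAPOR <- 461.5

#' Absolute water-vapor density from relative humidity and temperature
#'
#' Converts a relative-humidity reading at a given air temperature into an
#' absolute vapor density via the ideal gas law:
#' \eqn{\rho = (rh/100)\, e_s(T) / (R_v T_K)}, with \eqn{e_s} from
#' [saturation_vapor_pressure()], \eqn{R_v = 461.5} J kg\eqn{^{-1}}
#' K\eqn{^{-1}}, and the result expressed in g/m^3.
#'
#' @param rh Relative humidity in percent (0--100).
#' @param temp_c Air temperature in degrees Celsius.
#' @return Water-vapor density in g/m^3 (vectorised).
#' @examples
#' vapor_density(100, 25)  # ~23 g/m^3
#' vapor_density(50, 25)   # exactly half of that
#' @export
vapor_density <- function(rh, temp_c) {
  stopifnot(is.numeric(rh))
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100)) {
    stop("`rh` must be finite and within [0, 100] percent", call. = FALSE)
  }
  e_s_pa <- saturation_vapor_pressure(temp_c) * 100  # hPa -> Pa
  kg_m3 <- (rh / 100) * e_s_pa / (.R_VAPOR * (temp_c + 273.15))
  kg_m3 * 1000
}

#' A paired humidity/temperature sensor reading
#'
#' Bundles the readings of the two sensor pairs of an open-chamber
#' evaporimeter probe: relative humidity and temperature at a lower and an
#' upper position above the skin surface. The default heights (3 mm and 8 mm)
#' sit inside a 2 cm open cylinder probe.
#'
#' @param rh_lower,rh_upper Relative humidity in percent at the lower/upper
#'   sensor (0--100).
#' @param temp_lower,temp_upper Temperature in degrees Celsius at the
#'   lower/upper sensor.
#' @param height_lower,height_upper Sensor heights above the skin surface in
#'   meters; `height_upper` must exceed `height_lower` and both must be
#'   positive.
#' @return A one-row tibble of class `sensor_pair_reading`. A warning is
#'   raised (column `in_range` set to `FALSE`) when a reading falls outside
#'   the device operating range of 10--40 degrees C and 30--70 % relative
#'   humidity.
#' @export
sensor_pair_reading <- function(rh_lower, rh_upper, temp_lower, temp_upper,
                                height_lower = 0.003, height_upper = 0.008) {
  for (rh in list(rh_lower, rh_upper)) {
    if (!is.numeric(rh) || any(rh < 0 | rh > 100)) {
      stop("relative humidity must lie in [0, 100] percent", call. = FALSE)
    }
  }
  if (any(height_lower <= 0) || any(height_upper <= height_lower)) {
    stop("sensor heights must satisfy height_upper > height_lower > 0",
         call. = FALSE)
  }
  in_range <- temp_lower >= 10 & temp_lower <= 40 &
    temp_upper >= 10 & temp_upper <= 40 &
    rh_lower >= 30 & rh_lower <= 70 &
    rh_upper >= 30 & rh_upper <= 70
  if (any(!in_range)) {
    warning("reading outside device operating range (10-40 degC, 30-70 % RH)",
            call. = FALSE)
  }
  out <- tibble::tibble(
    rh_lower = rh_lower, rh_upper = rh_upper,
    temp_lower = temp_lower, temp_upper = temp_upper,
    height_lower = height_lower, height_upper = height_upper,
    in_range = in_range
  )
  class(out) <- c("sensor_pair_reading", class(out))
  out
}

#' TEWL flux from a two-sensor vapor-density gradient
#'
#' Applies Fick's first law of diffusion to a paired sensor reading: the
#' water flux off the skin is the diffusion coefficient times the vapor
#' density gradient between the lower and upper sensor,
#' \eqn{J = D (\rho_{lower} - \rho_{upper}) / (z_{upper} - z_{lower})},
#' converted from g m\eqn{^{-2}} s\eqn{^{-1}} to the conventional TEWL unit
#' g/h/m^2. The flux is positive when the air is moister near the skin.
#'
#' @param reading A [sensor_pair_reading()] (one or more rows).
#' @param diffusion_coeff Diffusion coefficient of water vapor in air,
#'   m^2/s. Default `2.49e-5` (approximately the value at 25 degrees C).
#' @return TEWL flux in g/h/m^2, one value per row of `reading`. No rounding
#'   is applied; round to the device's 0.1 g/h/m^2 reporting resolution only
#'   for display.
#' @examples
#' r <- sensor_pair_reading(rh_lower = 60, rh_upper = 45,
#'                          temp_lower = 30, temp_upper = 28)
#' tewl_from_gradient(r)
#' @export
tewl_from_gradient <- function(reading, diffusion_coeff = 2.49e-5) {
  stopifnot(is.data.frame(reading))
  if (!all(diffusion_coeff > 0)) {
    stop("`diffusion_coeff` must be positive", call. = FALSE)
  }
  dz <- reading$height_upper - reading$height_lower
  if (any(dz <= 0)) stop("zero or negative sensor separation", call. = FALSE)
  rho_lower <- vapor_density(reading$rh_lower, reading$temp_lower)
  rho_upper <- vapor_density(reading$rh_upper, reading$temp_upper)
  diffusion_coeff * (rho_lower - rho_upper) / dz * 3600
}

#' Stabilization stopping rule for a 1-Hz TEWL stream
#'
#' Walks a 1-Hz series of instantaneous TEWL readings maintaining a running
#' mean, and stops at the first second at which the standard deviation of
#' the most recent `window` readings about the current running mean falls
#' below `sd_threshold` (once at least `window` readings have been seen).
#' This reproduces the "measure until the SD of the current value relative
#' to the running mean is < 0.2" protocol of open-chamber devices. The
#' protocol wording does not pin down whether the running mean is windowed
#' or cumulative, so both are available: `mean_mode = "windowed"` (default;
#' mean of the trailing `window` readings, which tracks a still-drifting
#' probe and so reports a value close to the current flux) or
#' `"cumulative"` (mean of everything seen so far, which converges more
#' slowly after an initial drift).
#'
#' Non-convergence within `max_duration_s` seconds (or before the stream
#' ends) is not an error: the result carries `converged = FALSE` together
#' with the last running mean, so a caller can log and skip the site.
#'
#' @param stream Numeric vector of instantaneous TEWL readings, one per
#'   second, in g/h/m^2.
#' @param sd_threshold Stability threshold in g/h/m^2 (default 0.2).
#' @param window Number of most-recent readings entering the SD (default 10).
#' @param max_duration_s Give up after this many seconds (default 240).
#' @param mean_mode `"windowed"` (default) or `"cumulative"`; see Details.
#' @return A one-row tibble: `stable_value` (running mean at stop, g/h/m^2),
#'   `time_to_stability_s`, `converged` (logical), `sd_at_stop`, and
#'   `n_readings_used`.
#' @examples
#' stabilize_tewl(rep(10, 30))          # converges at t = window
#' stabilize_tewl(rep(c(0, 20), 120))   # never converges
#' @export
stabilize_tewl <- function(stream, sd_threshold = 0.2, window = 10,
                           max_duration_s = 240,
                           mean_mode = c("windowed", "cumulative")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot(is.numeric(stream))
  if (length(stream) < 1) stop("`stream` must be non-empty", call. = FALSE)
  if (sd_threshold <= 0) stop("`sd_threshold` must be > 0", call. = FALSE)
  if (window < 2) stop("`window` must be >= 2", call. = FALSE)
  n_max <- min(length(stream), max_duration_s)
  cum_mean <- cumsum(stream)[seq_len(n_max)] / seq_len(n_max)
  run_mean_at <- function(t) {
    if (mean_mode == "cumulative") {
      cum_mean[t]
    } else {
      mean(stream[(max(1L, t - window + 1L)):t])
    }
  }
  for (t in seq_len(n_max)) {
    if (t < window) next
    rm_t <- run_mean_at(t)
    win <- stream[(t - window + 1L):t]
    sd_t <- sqrt(mean((win - rm_t)^2))
    if (sd_t < sd_threshold) {
      return(tibble::tibble(
        stable_value = rm_t, time_to_stability_s = t,
        converged = TRUE, sd_at_stop = sd_t, n_readings_used = t
      ))
    }
  }
  rm_last <- run_mean_at(n_max)
  last_sd <- if (n_max >= window) {
    win <- stream[(n_max - window + 1L):n_max]
    sqrt(mean((win - rm_last)^2))
  } else {
    NA_real_
  }
  tibble::tibble(
    stable_value = rm_last, time_to_stability_s = n_max,
    converged = FALSE, sd_at_stop = last_sd, n_readings_used = n_max
  )
}

#' Read a raw evaporimeter stream from a delimited file
#'
#' Accepts either a two-column file (`seconds`, `tewl`) holding instantaneous
#' TEWL readings, or a six-column file (`seconds`, `rh_lower`, `rh_upper`,
#' `temp_lower`, `temp_upper` with fixed sensor heights) from which the flux
#' is computed via [tewl_from_gradient()].
#'
#' @param path Path to a delimited text file with a header.
#' @param height_lower,height_upper Sensor heights in meters, used for
#'   six-column files.
#' @param diffusion_coeff Diffusion coefficient passed to
#'   [tewl_from_gradient()].
#' @return A tibble with columns `seconds` and `tewl`.
#' @export
read_tewl_stream <- function(path, height_lower = 0.003, height_upper = 0.008,
                             diffusion_coeff = 2.49e-5) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("seconds", "tewl") %in% names(raw))) {
    return(tibble::as_tibble(raw[, c("seconds", "tewl")]))
  }
  needed <- c("seconds", "rh_lower", "rh_upper", "temp_lower", "temp_upper")
  if (!all(needed %in% names(raw))) {
    stop("stream file must have columns (seconds, tewl) or (",
         paste(needed, collapse = ", "), ")", call. = FALSE)
  }
  reading <- sensor_pair_reading(
    rh_lower = raw$rh_lower, rh_upper = raw$rh_upper,
    temp_lower = raw$temp_lower, temp_upper = raw$temp_upper,
    height_lower = height_lower, height_upper = height_upper
  )
  tibble::tibble(
    seconds = raw$seconds,
    tewl = tewl_from_gradient(reading, diffusion_coeff)
  )
}
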