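# Phenomenological model of the temperature field produced by a focused
# infrared laser in an aqueous specimen: linear power dependence at the focus,
# exponential spatial decay with a shared half-maximal distance, first-order
# step-response kinetics, and pulsed (duty-cycle) operation.

#' Construct a thermal profile
#'
#' A `thermal_profile` bundles the calibrated constants of the laser-heating
#' field: the focal heating slope (degC of elevation per mW of laser power),
#' the in-plane half-maximal heating distance (the distance from the focus at
#' which the temperature elevation falls to half its focal value), the ambient
#' (bath-controlled) temperature, and the first-order response time constant.
#'
#' The spatial field is parameterised base-2 in the half-distance:
#' \deqn{\Delta T(r) = k \, P \, 2^{-r / r_{1/2}}}
#' equivalently an exponential with decay length \eqn{r_{1/2}/\ln 2}. The
#' default time constant encodes the convention that heating reaches 95% of
#' its asymptote by 500 ms, i.e. `tau = 500 / log(20)` ms.
#'
#' @param slope Focal heating slope, degC per mW. Must be positive.
#' @param half_distance In-plane half-maximal heating distance, um. Positive.
#' @param ambient Ambient (bath) temperature, degC.
#' @param tau Response time constant, ms. Positive.
#' @param fit_diagnostics Optional tibble of per-parameter uncertainties from
#'   a fit (see [fit_power_slope()], [fit_spatial_profile()]).
#' @return An object of class `thermal_profile`.
#' @examples
#' prof <- thermal_profile(slope = 4, half_distance = 11, ambient = 20)
#' predict_focal_temp(3, prof) # 32 degC
#' @seealso [predict_focal_temp()], [predict_profile()], [heating_constants()]
#' @export
thermal_profile <- function(slope = 4, half_distance = 11, ambient = 20,
                            tau = 500 / log(20), fit_diagnostics = NULL) {
  stopifnot(is.numeric(slope), length(slope) == 1, slope > 0)
  stopifnot(is.numeric(half_distance), length(half_distance) == 1, half_distance > 0)
  stopifnot(is.numeric(ambient), length(ambient) == 1, is.finite(ambient))
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  structure(
    list(slope = slope, half_distance = half_distance, ambient = ambient,
         tau = tau, fit_diagnostics = fit_diagnostics),
    class = "thermal_profile"
  )
}

#' @export
print.thermal_profile <- function(x, ...) {
  cat("<thermal_profile>\n")
  cat(sprintf("  slope:         %.4g degC/mW\n", x$slope))
  cat(sprintf("  half-distance: %.4g um\n", x$half_distance))
  cat(sprintf("  ambient:       %.4g degC\n", x$ambient))
  cat(sprintf("  tau:           %.4g ms (95%% of asymptote at %.0f ms)\n",
              x$tau, x$tau * log(20)))
  invisible(x)
}

#' Reference heating constants
#'
#' Named constants used throughout the calibration: the focal heating slope is
#' carried both as the rounded published value (4 degC/mW) and as the raw
#' regression estimate (4.1 degC/mW); neither is silently preferred, and
#' functions take the slope explicitly via a [thermal_profile()].
#'
#' @return A tibble with columns `name`, `value`, `units`, `description`.
#' @export
heating_constants <- function() {
  tibble::tribble(
    ~name,                  ~value,          ~units,     ~description,
    "slope_rounded",        4,               "degC/mW",  "focal heating slope, rounded working value",
    "slope_regression",     4.1,             "degC/mW",  "focal heating slope, linear-regression estimate",
    "half_distance",        11,              "um",       "in-plane half-maximal heating distance",
    "sensitivity",          0.017,           "1/degC",   "mCherry fractional fluorescence decrease per degC",
    "sensitivity_range_lo", 15,              "degC",     "lower edge of the calibrated temperature range",
    "sensitivity_range_hi", 40,              "degC",     "upper edge of the calibrated temperature range",
    "tau_default",          500 / log(20),   "ms",       "response time constant (95% of asymptote at 500 ms)",
    "hs_band_lo",           32,              "degC",     "lower edge of the robust heat-shock induction band",
    "hs_band_hi",           34,              "degC",     "upper edge of the robust heat-shock induction band"
  )
}

#' Predict the absolute temperature at the laser focus
#'
#' @param power Laser power, mW (vectorised). Must be non-negative.
#' @param profile A [thermal_profile()].
#' @return Absolute focal temperature(s), degC: `ambient + slope * power`.
#' @examples
#' predict_focal_temp(3.0, thermal_profile(slope = 4, ambient = 20)) # 32
#' @export
predict_focal_temp <- function(power, profile) {
  stopifnot(inherits(profile, "thermal_profile"), all(power >= 0))
  profile$ambient + profile$slope * power
}

#' Predict the temperature elevation at a distance from the focus
#'
#' Evaluates the spatial heating field
#' \eqn{\Delta T(r) = k P \, 2^{-r/r_{1/2}}}. Profiles at different powers
#' differ only by a multiplicative scale, so `predict_profile(P, r)/P` is
#' independent of `P`.
#'
#' @param power Laser power, mW (vectorised with `r`).
#' @param r In-plane distance from the focus, um. Non-negative.
#' @param profile A [thermal_profile()].
#' @return Temperature elevation(s) above ambient, degC.
#' @export
predict_profile <- function(power, r, profile) {
  stopifnot(inherits(profile, "thermal_profile"), all(power >= 0), all(r >= 0))
  profile$slope * power * 2^(-r / profile$half_distance)
}

#' Fit the focal power-to-temperature slope
#'
#' Least-squares regression of focal temperature elevation on laser power. By
#' default the intercept is fixed at zero (the elevation must vanish at zero
#' power); a free intercept is available as a diagnostic.
#'
#' @param data A data frame with columns `power` (mW) and `temperature`
#'   (absolute focal temperature, degC).
#' @param ambient Ambient temperature subtracted before regression, degC.
#' @param free_intercept Fit an unconstrained intercept? Default `FALSE`.
#' @return An object of class `power_slope_fit` with elements `slope`,
#'   `slope_se`, `intercept`, `ambient`, `n`, and the underlying `lm` fit.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' d <- tibble::tibble(power = 1:5, temperature = 20 + 4 * (1:5))
#' fit_power_slope(d, ambient = 20)$slope # 4
#' @export
fit_power_slope <- function(data, ambient, free_intercept = FALSE) {
  stopifnot(is.data.frame(data), all(c("power", "temperature") %in% names(data)))
  if (dplyr::n_distinct(data$power) < 2) {
    stop("fit_power_slope() needs at least 2 distinct power levels", call. = FALSE)
  }
  d <- tibble::tibble(power = data$power, elevation = data$temperature - ambient)
  fit <- if (free_intercept) {
    stats::lm(elevation ~ power, data = d)
  } else {
    stats::lm(elevation ~ power + 0, data = d)
  }
  co <- quiet_perfect_fit(summary(fit))$coefficients
  structure(
    list(
      slope = unname(co["power", "Estimate"]),
      slope_se = unname(co["power", "Std. Error"]),
      intercept = if (free_intercept) unname(co["(Intercept)", "Estimate"]) else 0,
      ambient = ambient, free_intercept = free_intercept,
      n = nrow(d), fit = fit
    ),
    class = "power_slope_fit"
  )
}

#' @export
print.power_slope_fit <- function(x, ...) {
  cat("<power_slope_fit>\n")
  cat(sprintf("  slope: %.4g +/- %.3g degC/mW (n = %d, ambient %.4g degC)\n",
              x$slope, x$slope_se, x$n, x$ambient))
  if (x$free_intercept) cat(sprintf("  free intercept: %.4g degC\n", x$intercept))
  invisible(x)
}

# Heuristic starting values for the joint spatial fit: r_half from the first
# distance at which the binned elevation drops below half its maximum (first
# crossing wins); amplitudes from the innermost bin of each power.
spatial_fit_start <- function(data) {
  amps <- data |>
    dplyr::group_by(.data$power) |>
    dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  r_half0 <- data |>
    dplyr::group_by(.data$power) |>
    dplyr::arrange(.data$distance, .by_group = TRUE) |>
    dplyr::summarise(
      r0 = {
        half <- max(.data$delta_t) / 2
        below <- which(.data$delta_t < half)
        if (length(below) == 0) max(.data$distance) else .data$distance[below[1]]
      },
      .groups = "drop"
    ) |>
    dplyr::pull("r0") |>
    stats::median()
  list(r_half = max(r_half0, 1e-3), amplitudes = amps)
}

#' Jointly fit the spatial heating profile across powers
#'
#' Fits binned temperature-elevation measurements at two or more laser powers
#' to a family of exponential-decay curves sharing a single half-maximal
#' distance and differing only by per-power amplitudes:
#' \deqn{\Delta T_p(r) = A_p \, 2^{-r/r_{1/2}}}
#' with the far-field plateau fixed at zero elevation (ambient). The fit is a
#' Levenberg-Marquardt nonlinear least squares. A collapse diagnostic reports
#' how far the fitted amplitudes deviate from strict proportionality to power
#' (the multiplicative-scaling property of the field).
#'
#' @param data A data frame with columns `power` (mW), `distance` (um) and
#'   `delta_t` (temperature elevation above ambient, degC), typically the
#'   output of [bin_by_distance()] joined across powers.
#' @param profile Optional [thermal_profile()] supplying `ambient` and `tau`
#'   for the returned profile; defaults are used when absent.
#' @return An object of class `spatial_profile_fit`: `half_distance` (um) with
#'   standard error, a tibble `amplitudes` (`power`, `amplitude`,
#'   `amplitude_per_mw`), `slope` (amplitude-per-mW from a zero-intercept
#'   regression of amplitude on power), `collapse_residual` (RMS relative
#'   deviation of amplitudes from proportionality), the `profile` assembled
#'   from the fit, and the underlying `nls` object.
#' @examples
#' prof <- thermal_profile(slope = 4, half_distance = 11, ambient = 20)
#' d <- tidyr::expand_grid(power = c(2, 4), distance = seq(0, 30, 2)) |>
#'   dplyr::mutate(delta_t = predict_profile(power, distance, prof))
#' fit_spatial_profile(d)$half_distance # 11
#' @export
fit_spatial_profile <- function(data, profile = NULL) {
  stopifnot(is.data.frame(data),
            all(c("power", "distance", "delta_t") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (dplyr::n_distinct(data$power) < 2) {
    stop("fit_spatial_profile() needs measurements at >= 2 powers", call. = FALSE)
  }
  bins_per_power <- data |> dplyr::count(.data$power)
  if (any(bins_per_power$n < 4)) {
    stop("fit_spatial_profile() needs >= 4 distance bins per power", call. = FALSE)
  }
  powers <- sort(unique(data$power))
  pidx <- match(data$power, powers)
  start0 <- spatial_fit_start(data)
  start <- c(stats::setNames(start0$amplitudes$delta_t[match(powers, start0$amplitudes$power)],
                             paste0("A", seq_along(powers))),
             r_half = start0$r_half)
  # Indexed-amplitude model: pidx maps each row to its power level so a single
  # nlsLM call fits all powers jointly with one shared r_half.
  fml <- stats::as.formula(paste0(
    "delta_t ~ c(", paste0("A", seq_along(powers), collapse = ", "),
    ")[pidx] * 2^(-distance / r_half)"
  ))
  df <- data.frame(delta_t = data$delta_t, distance = data$distance, pidx = pidx)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fml, data = df, start = as.list(start),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf(
        "fit_spatial_profile() did not converge: %s [starting values: %s]",
        conditionMessage(e),
        paste(sprintf("%s=%.3g", names(start), start), collapse = ", ")
      ), call. = FALSE)
    }
  )
  co <- summary(fit)$coefficients
  r_half <- unname(co["r_half", "Estimate"])
  amps <- tibble::tibble(
    power = powers,
    amplitude = unname(co[paste0("A", seq_along(powers)), "Estimate"]),
    amplitude_se = unname(co[paste0("A", seq_along(powers)), "Std. Error"])
  ) |>
    dplyr::mutate(amplitude_per_mw = .data$amplitude / .data$power)
  slope <- sum(amps$amplitude * amps$power) / sum(amps$power^2)
  collapse <- sqrt(mean((amps$amplitude / (slope * amps$power) - 1)^2))
  ambient <- if (!is.null(profile)) profile$ambient else 20
  tau <- if (!is.null(profile)) profile$tau else 500 / log(20)
  diag <- tibble::tibble(
    term = c("r_half", paste0("A_", powers)),
    estimate = c(r_half, amps$amplitude),
    std_error = c(unname(co["r_half", "Std. Error"]), amps$amplitude_se)
  )
  structure(
    list(
      half_distance = r_half,
      half_distance_se = unname(co["r_half", "Std. Error"]),
      amplitudes = amps,
      slope = slope,
      collapse_residual = collapse,
      profile = thermal_profile(slope = slope, half_distance = r_half,
                                ambient = ambient, tau = tau,
                                fit_diagnostics = diag),
      data = data,
      fit = fit
    ),
    class = "spatial_profile_fit"
  )
}

#' @export
print.spatial_profile_fit <- function(x, ...) {
  cat("<spatial_profile_fit>\n")
  cat(sprintf("  half-distance: %.4g +/- %.3g um\n",
              x$half_distance, x$half_distance_se))
  cat(sprintf("  slope (amplitude/power): %.4g degC/mW\n", x$slope))
  cat(sprintf("  scaling-collapse residual: %.3g (RMS relative)\n",
              x$collapse_residual))
  print(x$amplitudes)
  invisible(x)
}

#' First-order step response of the focal temperature
#'
#' Temperature elevation kinetics after switching the laser on (`"heating"`,
#' \eqn{S(1 - e^{-t/\tau})}) or off (`"cooling"`, \eqn{S e^{-t/\tau}}). With
#' the default profile time constant, heating reaches 95% of its asymptote at
#' 500 ms and decays with the same kinetics.
#'
#' @param t Time since the switch, ms (vectorised). Non-negative.
#' @param steady_elevation Asymptotic elevation, degC.
#' @param tau Time constant, ms.
#' @param phase `"heating"` (default) or `"cooling"`.
#' @return Temperature elevation(s), degC.
#' @export
step_response <- function(t, steady_elevation, tau = 500 / log(20),
                          phase = c("heating", "cooling")) {
  phase <- match.arg(phase)
  stopifnot(all(t >= 0), tau > 0)
  if (phase == "heating") steady_elevation * (1 - exp(-t / tau))
  else steady_elevation * exp(-t / tau)
}

#' Construct a laser pulse schedule
#'
#' @param frequency Pulse repetition rate, Hz.
#' @param pulse_width Duration of each pulse, ms.
#' @param peak_power Power during a pulse, mW.
#' @param total_duration Total exposure, s.
#' @param mode `"pulsed"` or `"continuous"`. Continuous mode has duty 1.
#' @return An object of class `pulse_schedule`.
#' @examples
#' pulse_schedule(6, 8.3, 13, 10) # ablation-style pulsing, duty ~ 5%
#' @export
pulse_schedule <- function(frequency, pulse_width, peak_power, total_duration,
                           mode = c("pulsed", "continuous")) {
  mode <- match.arg(mode)
  if (mode == "continuous") {
    frequency <- 1
    pulse_width <- 1000
  }
  stopifnot(frequency > 0, pulse_width > 0, peak_power > 0, total_duration > 0)
  if (frequency * pulse_width > 1000) {
    stop("invalid pulse schedule: duty cycle exceeds 1 (frequency * pulse_width > 1000 ms/s)",
         call. = FALSE)
  }
  structure(
    list(frequency = frequency, pulse_width = pulse_width,
         peak_power = peak_power, total_duration = total_duration, mode = mode),
    class = "pulse_schedule"
  )
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat(sprintf("<pulse_schedule> %s: %g Hz, %g ms pulses, %g mW peak, %g s total\n",
              x$mode, x$frequency, x$pulse_width, x$peak_power, x$total_duration))
  invisible(x)
}

#' Summarise the thermal exposure of a pulse schedule
#'
#' Computes the duty cycle (`frequency * pulse_width / 1000`), the
#' time-averaged power (`peak_power * duty`), and the peak focal temperature
#' reached during a pulse. When the pulse is short relative to the thermal
#' response (`pulse_width < 3 * tau`) the peak elevation is attenuated by the
#' step-response factor \eqn{1 - e^{-w/\tau}}; longer pulses reach the full
#' steady-state elevation.
#'
#' @param schedule A [pulse_schedule()].
#' @param profile A [thermal_profile()].
#' @return A one-row tibble: `duty_cycle`, `averaged_power_mw`,
#'   `peak_focal_temp_c`, `steady_focal_temp_c`.
#' @export
pulsed_exposure <- function(schedule, profile) {
  stopifnot(inherits(schedule, "pulse_schedule"), inherits(profile, "thermal_profile"))
  duty <- schedule$frequency * schedule$pulse_width / 1000
  if (schedule$mode == "continuous") duty <- 1
  averaged <- schedule$peak_power * duty
  steady_elev <- profile$slope * schedule$peak_power
  peak_elev <- if (schedule$pulse_width < 3 * profile$tau && schedule$mode == "pulsed") {
    step_response(schedule$pulse_width, steady_elev, profile$tau)
  } else {
    steady_elev
  }
  tibble::tibble(
    duty_cycle = duty,
    averaged_power_mw = averaged,
    peak_focal_temp_c = profile$ambient + peak_elev,
    steady_focal_temp_c = profile$ambient + steady_elev
  )
}
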