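# broom-style tidiers for the fitted objects.

lasertherm_quiet_summary <- function(fit) quiet_perfect_fit(summary(fit))

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calibration-curve fit
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `sensitivity`, `std_error`, `percent_per_c`.
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = "sensitivity",
    estimate = x$sensitivity,
    std_error = x$sensitivity_se,
    percent_per_c = 100 * x$sensitivity
  )
}

#' @rdname tidy.calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    r_squared = x$fit_r_squared,
    n_points = x$n_points,
    ref_temp = x$ref_temp,
    valid_lo = x$valid_range[1],
    valid_hi = x$valid_range[2]
  )
}

#' Tidy a power-slope fit
#'
#' @param x A `power_slope_fit`.
#' @param ... Unused.
#' @return A tibble of coefficients.
#' @export
tidy.power_slope_fit <- function(x, ...) {
  out <- tibble::tibble(term = "slope", estimate = x$slope,
                        std_error = x$slope_se)
  if (x$free_intercept) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(term = "intercept", estimate = x$intercept,
                          std_error = lasertherm_quiet_summary(x$fit)$coefficients["(Intercept)", "Std. Error"]))
  }
  out
}

#' @rdname tidy.power_slope_fit
#' @export
glance.power_slope_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = lasertherm_quiet_summary(x$fit)$r.squared,
    sigma = lasertherm_quiet_summary(x$fit)$sigma,
    n = x$n,
    ambient = x$ambient
  )
}

#' Tidy a joint spatial-profile fit
#'
#' @param x A `spatial_profile_fit`.
#' @param ... Unused.
#' @return A tibble with the shared half-distance and per-power amplitudes.
#' @export
tidy.spatial_profile_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "half_distance", estimate = x$half_distance,
                   std_error = x$half_distance_se),
    tibble::tibble(term = paste0("amplitude_", x$amplitudes$power, "mW"),
                   estimate = x$amplitudes$amplitude,
                   std_error = x$amplitudes$amplitude_se)
  )
}

#' @rdname tidy.spatial_profile_fit
#' @export
glance.spatial_profile_fit <- function(x, ...) {
  tibble::tibble(
    half_distance = x$half_distance,
    slope = x$slope,
    collapse_residual = x$collapse_residual,
    sigma = lasertherm_quiet_summary(x$fit)$sigma,
    n = nrow(x$data)
  )
}

#' Tidy a temperature map into pixel records
#'
#' @param x A `temperature_map`.
#' @param ... Unused.
#' @return A tibble: `x`, `y` (um, grid-pixel centres), `delta_t` (degC,
#'   `NA` where masked), `valid`.
#' @export
tidy.temperature_map <- function(x, ...) {
  nr <- nrow(x$delta_t); nc <- ncol(x$delta_t)
  tibble::tibble(
    x = rep((seq_len(nc) - 0.5) * x$pixel_size, each = nr),
    y = rep((seq_len(nr) - 0.5) * x$pixel_size, times = nc),
    delta_t = as.vector(x$delta_t),
    valid = as.vector(x$mask)
  )
}

#' Tidy an induction or ablation plan
#'
#' @param x An `induction_plan`.
#' @param ... Unused.
#' @return A tibble of plan parameters, one row per field.
#' @export
tidy.induction_plan <- function(x, ...) {
  tibble::tibble(
    parameter = c("mode", "feasible", "power_mw", "ambient_c",
                  "predicted_focal_c", "predicted_at_neighbor_c",
                  "neighbor_distance_um", "band_lo_c", "band_hi_c"),
    value = c(x$mode, x$feasible, x$power, x$ambient, x$predicted_focal,
              x$predicted_at_neighbor, x$neighbor_distance,
              x$threshold_band[1], x$threshold_band[2])
  )
}

#' Tidy an outgrowth comparison
#'
#' @param x An `outgrowth_comparison`.
#' @param ... Unused.
#' @return The comparison tibble (onset and rate rows with bootstrap CIs).
#' @export
tidy.outgrowth_comparison <- function(x, ...) x$comparison
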