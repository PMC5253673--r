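# ggplot2 graphics for the main result types.

#' Plot a temperature-elevation map
#'
#' @param object A `temperature_map`.
#' @param ... Unused.
#' @return A ggplot raster of the elevation field (masked pixels blank).
#' @export
autoplot.temperature_map <- function(object, ...) {
  d <- tidy.temperature_map(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$delta_t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey85",
                                  name = expression(Delta * T ~ "(°C)")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Temperature elevation (base %g °C)",
                                  object$base_temp)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration-curve fit
#'
#' @param object A `calibration_curve` produced by [fit_sensitivity()].
#' @param ... Unused.
#' @return A ggplot of normalised fluorescence versus temperature with the
#'   fitted line.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  if (is.null(object$data)) {
    stop("no underlying data: this calibration was constructed, not fitted",
         call. = FALSE)
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$temperature, y = .data$f_norm)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::labs(x = "Temperature (°C)",
                  y = sprintf("Fluorescence (normalised to %g °C)",
                              object$ref_temp),
                  title = sprintf("Sensitivity %.2f%%/°C (R² = %.4f)",
                                  100 * object$sensitivity, object$fit_r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a joint spatial-profile fit
#'
#' @param object A `spatial_profile_fit`.
#' @param ... Unused.
#' @return A ggplot of binned elevations versus distance with the fitted
#'   shared-half-distance decay curves, one per power.
#' @export
autoplot.spatial_profile_fit <- function(object, ...) {
  grid <- tidyr::expand_grid(
    power = object$amplitudes$power,
    distance = seq(0, max(object$data$distance), length.out = 120)
  ) |>
    dplyr::left_join(object$amplitudes[, c("power", "amplitude")], by = "power") |>
    dplyr::mutate(delta_t = .data$amplitude *
                    2^(-.data$distance / object$half_distance))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$distance, y = .data$delta_t,
                               colour = factor(.data$power))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$half_distance, linetype = "dashed") +
    ggplot2::labs(x = "Distance from focus (µm)",
                  y = expression(Delta * T ~ "(°C)"),
                  colour = "Power (mW)",
                  title = sprintf("Half-maximal heating at %.1f µm",
                                  object$half_distance)) +
    ggplot2::theme_minimal()
}

#' Plot growth curves by group
#'
#' @param curves A data frame with columns `stage`, `length` and `curve_id`
#'   (and optionally `group`), or an `outgrowth_comparison` whose per-curve
#'   data are to be shown.
#' @return A ggplot of neurite length versus developmental stage.
#' @export
plot_growth_curves <- function(curves) {
  stopifnot(is.data.frame(curves),
            all(c("stage", "length", "curve_id") %in% names(curves)))
  aes <- if ("group" %in% names(curves)) {
    ggplot2::aes(x = .data$stage, y = .data$length,
                 group = .data$curve_id, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$stage, y = .data$length, group = .data$curve_id)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Developmental stage (tail-to-head ratio)",
                  y = "Neurite length (µm)") +
    ggplot2::theme_minimal()
}
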