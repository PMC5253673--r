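# Induction/ablation planning: choose laser power and ambient temperature so
# the target cell sits inside the heat-shock band (induction) or above a
# lethal temperature (ablation) while the nearest neighbour stays below the
# induction threshold. Geometry is reduced to a single nearest-neighbour
# distance; full per-cell classification is available via classify_cells().

new_induction_plan <- function(mode, power, ambient, duration, threshold_band,
                               predicted_focal, predicted_at_neighbor,
                               neighbor_distance, feasible, diagnostic = NULL,
                               schedule = NULL, lethal_temp = NULL,
                               power_range = NULL, profile = NULL) {
  structure(
    list(mode = mode, power = power, ambient = ambient, duration = duration,
         threshold_band = threshold_band, predicted_focal = predicted_focal,
         predicted_at_neighbor = predicted_at_neighbor,
         neighbor_distance = neighbor_distance, feasible = feasible,
         diagnostic = diagnostic, schedule = schedule,
         lethal_temp = lethal_temp, power_range = power_range,
         profile = profile),
    class = "induction_plan"
  )
}

#' @export
print.induction_plan <- function(x, ...) {
  cat(sprintf("<induction_plan> mode: %s, %s\n", x$mode,
              if (x$feasible) "FEASIBLE" else "INFEASIBLE"))
  if (!is.null(x$power_range)) {
    cat(sprintf("  feasible power range: [%.3g, %.3g] mW\n",
                x$power_range[1], x$power_range[2]))
  }
  cat(sprintf("  power: %.3g mW at ambient %.3g degC\n", x$power, x$ambient))
  cat(sprintf("  predicted focal: %.3g degC; at neighbour (%.3g um): %.3g degC\n",
              x$predicted_focal, x$neighbor_distance, x$predicted_at_neighbor))
  cat(sprintf("  threshold band: [%g, %g] degC\n",
              x$threshold_band[1], x$threshold_band[2]))
  if (!is.null(x$lethal_temp)) cat(sprintf("  lethal temperature: %g degC\n", x$lethal_temp))
  if (!is.null(x$schedule)) print(x$schedule)
  if (!is.null(x$diagnostic)) cat(sprintf("  diagnostic: %s\n", x$diagnostic))
  invisible(x)
}

#' Plan a single-cell heat-shock induction
#'
#' Finds the laser power interval that puts the focal temperature inside the
#' heat-shock band, `[(T_low - ambient)/slope, (T_high - ambient)/slope]`,
#' and checks that the nearest neighbouring cell stays below the induction
#' threshold. The plan power defaults to the interval midpoint (symmetric
#' margin against under- and over-shoot); `edge = "low"` picks the lower edge.
#'
#' @param profile A [thermal_profile()]; its `ambient` is overridden by the
#'   `ambient` argument when supplied.
#' @param threshold_band Heat-shock band `c(low, high)`, degC. Default
#'   `c(32, 34)` (robust induction with high viability for a 5-min exposure).
#' @param neighbor_distance Distance from the focus to the nearest cell that
#'   must remain sub-threshold, um. No default is assumed for the geometry:
#'   it must be supplied.
#' @param ambient Ambient (bath) temperature, degC. Default: profile ambient.
#' @param duration Exposure duration, min. Default 5.
#' @param edge `"mid"` (default) or `"low"`: which point of the feasible
#'   power interval to adopt.
#' @return An `induction_plan`. Infeasible configurations (ambient at or above
#'   the band, or no power keeping the neighbour sub-threshold) are returned
#'   with `feasible = FALSE` and a diagnostic, not as errors.
#' @examples
#' prof <- thermal_profile(slope = 4, half_distance = 11, ambient = 20)
#' plan_induction(prof, c(32, 34), neighbor_distance = 11)
#' @export
plan_induction <- function(profile, threshold_band = c(32, 34),
                           neighbor_distance, ambient = profile$ambient,
                           duration = 5, edge = c("mid", "low")) {
  stopifnot(inherits(profile, "thermal_profile"),
            length(threshold_band) == 2, threshold_band[1] < threshold_band[2],
            neighbor_distance >= 0)
  edge <- match.arg(edge)
  t_low <- threshold_band[1]; t_high <- threshold_band[2]
  if (ambient >= t_low) {
    return(new_induction_plan(
      "induction", NA_real_, ambient, duration, threshold_band,
      NA_real_, NA_real_, neighbor_distance, feasible = FALSE,
      diagnostic = sprintf(
        "ambient %g degC is at or above the band lower edge %g degC: everything is above threshold",
        ambient, t_low),
      profile = profile))
  }
  p_range <- c(t_low - ambient, t_high - ambient) / profile$slope
  power <- if (edge == "mid") mean(p_range) else p_range[1]
  predicted_focal <- ambient + profile$slope * power
  predicted_neigh <- ambient + predict_profile(power, neighbor_distance, profile)
  feasible <- predicted_neigh < t_low
  diag <- if (!feasible) {
    sprintf("neighbour at %g um predicted at %.3g degC >= band lower edge %g degC",
            neighbor_distance, predicted_neigh, t_low)
  }
  new_induction_plan("induction", power, ambient, duration, threshold_band,
                     predicted_focal, predicted_neigh, neighbor_distance,
                     feasible, diag, power_range = p_range, profile = profile)
}

#' Classify cells under an induction plan
#'
#' Predicts the absolute temperature of each cell from its distance to the
#' laser focus and labels it `"induced"` when that temperature reaches the
#' band lower edge (induction mode) or the lethal temperature (ablation mode
#' labels `"ablated"`/`"induced"`/`"sub-threshold"`).
#'
#' @param cells A data frame of cell positions in um with columns `x`, `y`
#'   (and optionally `z`).
#' @param plan A feasible [plan_induction()] or [plan_ablation()] result.
#' @param profile A [thermal_profile()].
#' @param focus Laser focus position, um, same dimensionality as `cells`.
#' @return The input tibble with `distance_to_focus`, `predicted_temp` (degC)
#'   and `label` columns appended.
#' @export
classify_cells <- function(cells, plan, profile, focus) {
  stopifnot(is.data.frame(cells), all(c("x", "y") %in% names(cells)),
            inherits(plan, "induction_plan"), inherits(profile, "thermal_profile"))
  if (!isTRUE(plan$feasible)) stop("plan is infeasible", call. = FALSE)
  dims <- intersect(c("x", "y", "z"), names(cells))
  stopifnot(length(focus) == length(dims))
  pos <- as.matrix(cells[, dims])
  dist <- sqrt(rowSums((pos - matrix(focus, nrow(pos), length(dims), byrow = TRUE))^2))
  peak_power <- if (!is.null(plan$schedule)) plan$schedule$peak_power else plan$power
  predicted <- plan$ambient + predict_profile(peak_power, dist, profile)
  label <- if (plan$mode == "ablation") {
    dplyr::case_when(
      predicted >= plan$lethal_temp ~ "ablated",
      predicted >= plan$threshold_band[1] ~ "induced",
      TRUE ~ "sub-threshold"
    )
  } else {
    ifelse(predicted >= plan$threshold_band[1], "induced", "sub-threshold")
  }
  tibble::as_tibble(cells) |>
    dplyr::mutate(distance_to_focus = dist, predicted_temp = predicted,
                  label = label)
}

#' Plan a pulsed-laser single-cell ablation
#'
#' Chooses a peak power reaching at least the lethal temperature at the focus
#' and verifies, via the time-averaged power of the pulse schedule, that the
#' nearest neighbour remains below the induction threshold. The default
#' schedule is 6 Hz pulsing with 8.3 ms pulses for 10 s (duty ~5%), which
#' suppresses off-target heat accumulation.
#'
#' @param profile A [thermal_profile()].
#' @param lethal_temp Focal temperature required to kill the target, degC.
#'   Default 50 (a documented convention; prior continuous-exposure protocols
#'   computed at 50-70 degC destroy cells outright). Must exceed the
#'   induction band upper edge.
#' @param induction_band Heat-shock band `c(low, high)`, degC.
#' @param neighbor_distance Distance to the nearest cell that must not be
#'   induced, um. Must be supplied.
#' @param ambient Ambient temperature, degC. Default: profile ambient.
#' @param peak_power Peak pulse power, mW. Default: the minimum power
#'   reaching `lethal_temp`, `(lethal_temp - ambient)/slope`.
#' @param schedule A [pulse_schedule()]. Default 6 Hz / 8.3 ms / 10 s at
#'   `peak_power`.
#' @return An `induction_plan` with `mode = "ablation"` and the schedule
#'   attached. Feasibility requires the time-averaged temperature at the
#'   neighbour to stay below the induction threshold.
#' @export
plan_ablation <- function(profile, lethal_temp = 50, induction_band = c(32, 34),
                          neighbor_distance, ambient = profile$ambient,
                          peak_power = NULL, schedule = NULL) {
  stopifnot(inherits(profile, "thermal_profile"),
            length(induction_band) == 2, neighbor_distance >= 0)
  if (lethal_temp <= induction_band[2]) {
    stop("lethal_temp must exceed the induction band upper edge", call. = FALSE)
  }
  min_peak <- (lethal_temp - ambient) / profile$slope
  if (min_peak <= 0) {
    return(new_induction_plan(
      "ablation", NA_real_, ambient, NA_real_, induction_band, NA_real_,
      NA_real_, neighbor_distance, feasible = FALSE,
      diagnostic = "ambient already at or above the lethal temperature",
      lethal_temp = lethal_temp, profile = profile))
  }
  if (is.null(peak_power)) peak_power <- min_peak
  if (peak_power < min_peak) {
    return(new_induction_plan(
      "ablation", peak_power, ambient, NA_real_, induction_band,
      ambient + profile$slope * peak_power, NA_real_, neighbor_distance,
      feasible = FALSE,
      diagnostic = sprintf("peak power %.3g mW below the minimum %.3g mW reaching %g degC",
                           peak_power, min_peak, lethal_temp),
      lethal_temp = lethal_temp, profile = profile))
  }
  if (is.null(schedule)) {
    schedule <- pulse_schedule(frequency = 6, pulse_width = 8.3,
                               peak_power = peak_power, total_duration = 10)
  }
  exposure <- pulsed_exposure(schedule, profile)
  predicted_focal <- ambient + profile$slope * schedule$peak_power
  avg_neigh <- ambient +
    predict_profile(exposure$averaged_power_mw, neighbor_distance, profile)
  feasible <- avg_neigh < induction_band[1]
  diag <- if (!feasible) {
    sprintf("time-averaged neighbour temperature %.3g degC reaches the induction threshold %g degC",
            avg_neigh, induction_band[1])
  }
  plan <- new_induction_plan(
    "ablation", schedule$peak_power, ambient, schedule$total_duration / 60,
    induction_band, predicted_focal, avg_neigh, neighbor_distance, feasible,
    diag, schedule = schedule, lethal_temp = lethal_temp, profile = profile)
  plan$min_peak_power <- min_peak
  plan$exposure <- exposure
  plan
}
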