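# Morphometrics of labelled cells: 3D polyline neurite lengths, a tail-to-head
# developmental-stage clock, growth curves, bootstrap group comparisons of
# outgrowth onset and rate, paired division-timing statistics, and
# power-normalised reporter-induction kinetics.

#' Length of a 3D polyline
#'
#' Sums the Euclidean distances between consecutive annotated points:
#' `D_3D = sqrt(dx^2 + dy^2 + dz^2)` per segment. A single point has length 0.
#'
#' @param points An ordered set of 3D coordinates in um: a matrix with 3
#'   columns or a data frame with columns `x`, `y`, `z` (a `point_index`
#'   column, when present, fixes the order).
#' @return Total length, um.
#' @examples
#' polyline_length(rbind(c(0, 0, 0), c(3, 4, 0))) # 5
#' @export
polyline_length <- function(points) {
  if (is.data.frame(points)) {
    if ("point_index" %in% names(points)) {
      points <- points[order(points$point_index), ]
    }
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  stopifnot(is.matrix(points), ncol(points) == 3, nrow(points) >= 1)
  if (any(!is.finite(points))) stop("non-finite coordinate", call. = FALSE)
  if (nrow(points) == 1) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Stage calibration anchors
#'
#' The tail-to-head distance of the embryo serves as a developmental clock:
#' the measure at the comma stage maps to 0 and at the 2-fold stage to 1.
#'
#' @param comma_metric Tail-to-head measure at comma stage, um. Positive.
#' @param twofold_metric Tail-to-head measure at 2-fold stage, um. Positive,
#'   different from `comma_metric`.
#' @return An object of class `stage_calibration`.
#' @export
stage_calibration <- function(comma_metric, twofold_metric) {
  stopifnot(comma_metric > 0, twofold_metric > 0)
  if (comma_metric == twofold_metric) {
    stop("comma and 2-fold anchors must differ", call. = FALSE)
  }
  structure(list(comma_metric = comma_metric, twofold_metric = twofold_metric),
            class = "stage_calibration")
}

#' Map a tail-to-head measure to a developmental stage
#'
#' Linear interpolation between the calibration anchors: the comma-stage
#' measure maps to 0 and the 2-fold measure to 1. Values outside `[0, 1]`
#' (pre-comma or post-2-fold) are clamped; the `clamped` attribute flags them.
#'
#' @param tail_to_head Tail-to-head measure(s), um.
#' @param calib A [stage_calibration()].
#' @return Stage value(s) in `[0, 1]` with a logical `clamped` attribute.
#' @export
stage_ratio <- function(tail_to_head, calib) {
  stopifnot(inherits(calib, "stage_calibration"))
  raw <- (tail_to_head - calib$comma_metric) /
    (calib$twofold_metric - calib$comma_metric)
  clamped <- raw < 0 | raw > 1
  if (any(clamped)) {
    warning(sprintf("%d stage value(s) outside [0, 1] clamped", sum(clamped)),
            call. = FALSE)
  }
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clamped") <- clamped
  out
}

#' Growth curve of a neurite track
#'
#' Computes the polyline length at each staged timepoint of a track.
#' Timepoints without a stage (e.g. the neurite was not visible) are omitted,
#' not interpolated.
#'
#' @param track A data frame with columns `time`, `stage`, `point_index`,
#'   `x`, `y`, `z`, e.g. from [gen_neurite_tracks()].
#' @return A tibble with columns `time`, `stage`, `length` (um), one row per
#'   staged timepoint.
#' @export
growth_curve <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("time", "stage", "x", "y", "z") %in% names(track)))
  staged <- dplyr::filter(track, !is.na(.data$stage))
  if (nrow(staged) == 0) stop("track has no staged timepoints", call. = FALSE)
  st <- staged |> dplyr::distinct(.data$time, .data$stage) |> dplyr::arrange(.data$time)
  if (is.unsorted(st$stage)) {
    stop("stages must be non-decreasing in time", call. = FALSE)
  }
  staged |>
    dplyr::group_by(.data$time, .data$stage) |>
    dplyr::summarise(
      length = polyline_length(dplyr::pick(dplyr::any_of(c("point_index", "x", "y", "z")))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time)
}

# Per-curve onset stage (first stage with length above threshold) and
# post-onset growth rate (OLS slope of length on stage). NA when the curve
# never exceeds the threshold.
curve_onset_rate <- function(curve, threshold) {
  above <- curve$length > threshold
  if (!any(above)) return(c(onset = NA_real_, rate = NA_real_))
  onset <- curve$stage[which(above)[1]]
  grown <- curve[above, ]
  rate <- if (nrow(grown) >= 2 && stats::var(grown$stage) > 0) {
    unname(stats::coef(stats::lm(length ~ stage, data = grown))["stage"])
  } else NA_real_
  c(onset = onset, rate = rate)
}

#' Compare neurite outgrowth between two groups of embryos
#'
#' Estimates the outgrowth onset stage (first stage with length above a small
#' threshold) and the post-onset growth rate per curve, and compares the
#' group means with a seeded percentile bootstrap.
#'
#' @param group_a,group_b Lists of growth curves (tibbles from
#'   [growth_curve()]), or single data frames with a `curve_id` column.
#'   Each group needs at least 2 curves.
#' @param threshold Outgrowth-initiation length threshold, um. Default 1.
#' @param n_boot Bootstrap resamples. Default 1000.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level. Default 0.95.
#' @return An object of class `outgrowth_comparison`: a tibble `comparison`
#'   (`quantity`, `mean_a`, `mean_b`, `difference`, `ci_lo`, `ci_hi`) for the
#'   onset stage and growth rate, plus the per-curve estimates. Curves never
#'   exceeding the threshold are excluded with a warning.
#' @export
compare_outgrowth <- function(group_a, group_b, threshold = 1, n_boot = 1000,
                              seed = 1L, conf_level = 0.95) {
  as_curve_list <- function(g) {
    if (is.data.frame(g)) {
      stopifnot("curve_id" %in% names(g))
      g <- split(g, g$curve_id)
    }
    g
  }
  group_a <- as_curve_list(group_a)
  group_b <- as_curve_list(group_b)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("compare_outgrowth() needs >= 2 curves per group", call. = FALSE)
  }
  per_curve <- function(curves, label) {
    est <- t(vapply(curves, curve_onset_rate, numeric(2), threshold = threshold))
    out <- tibble::tibble(group = label, curve = seq_len(nrow(est)),
                          onset = est[, "onset"], rate = est[, "rate"])
    dropped <- sum(is.na(out$onset))
    if (dropped > 0) {
      warning(sprintf("%d curve(s) in group %s never exceed the %g um threshold; excluded",
                      dropped, label, threshold), call. = FALSE)
    }
    dplyr::filter(out, !is.na(.data$onset))
  }
  ests <- dplyr::bind_rows(per_curve(group_a, "A"), per_curve(group_b, "B"))
  if (sum(ests$group == "A") < 2 || sum(ests$group == "B") < 2) {
    stop("fewer than 2 usable curves in a group after threshold exclusion",
         call. = FALSE)
  }
  boot_diff <- function(xa, xb) {
    withr::with_seed(as.integer(seed), {
      replicate(n_boot,
        mean(sample(xb, replace = TRUE), na.rm = TRUE) -
          mean(sample(xa, replace = TRUE), na.rm = TRUE))
    })
  }
  alpha <- (1 - conf_level) / 2
  summarise_q <- function(qty) {
    xa <- ests[[qty]][ests$group == "A"]
    xb <- ests[[qty]][ests$group == "B"]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    bd <- boot_diff(xa, xb)
    tibble::tibble(
      quantity = qty, mean_a = mean(xa), mean_b = mean(xb),
      difference = mean(xb) - mean(xa),
      ci_lo = unname(stats::quantile(bd, alpha)),
      ci_hi = unname(stats::quantile(bd, 1 - alpha))
    )
  }
  structure(
    list(comparison = dplyr::bind_rows(summarise_q("onset"), summarise_q("rate")),
         per_curve = ests, threshold = threshold, n_boot = n_boot,
         conf_level = conf_level),
    class = "outgrowth_comparison"
  )
}

#' @export
print.outgrowth_comparison <- function(x, ...) {
  cat(sprintf("<outgrowth_comparison> %d vs %d curves, %d bootstrap resamples, %g%% CI\n",
              sum(x$per_curve$group == "A"), sum(x$per_curve$group == "B"),
              x$n_boot, 100 * x$conf_level))
  print(x$comparison)
  invisible(x)
}

#' Division-timing statistics for heated versus control cells
#'
#' In paired mode, reports the mean signed delay `treated_time -
#' control_time` across embryos. In control mode (no treatment; left/right
#' homologues), reports the mean absolute left-right difference. When cycle
#' columns are present, also reports the mean per-embryo percent cycle-time
#' increase `(treated_cycle - control_cycle) / control_cycle`.
#'
#' @param records A data frame with columns `treated_time` and `control_time`
#'   (min), optionally `treated_cycle` and `control_cycle` (min).
#' @param paired `TRUE` (default): signed treated-minus-control delays.
#'   `FALSE`: absolute differences (untreated left/right variability).
#' @param percent_cycle Compute the percent cycle increase? Default: `TRUE`
#'   when the cycle columns are present. Requesting it without them errors.
#' @return A one-row tibble: `mean_delay` (min), `sd_delay`, `n`,
#'   `percent_cycle_increase` (%, `NA` when not computed). The per-embryo
#'   differences are attached as the `per_embryo` attribute.
#' @export
division_delay_stats <- function(records, paired = TRUE,
                                 percent_cycle = all(c("treated_cycle", "control_cycle") %in% names(records))) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("treated_time", "control_time") %in% names(records)))
  if (any(records$treated_time < 0 | records$control_time < 0)) {
    stop("division times must be non-negative", call. = FALSE)
  }
  diffs <- records$treated_time - records$control_time
  if (!paired) diffs <- abs(diffs)
  pct <- NA_real_
  if (isTRUE(percent_cycle)) {
    if (!all(c("treated_cycle", "control_cycle") %in% names(records))) {
      stop("cycle columns absent: cannot compute percent cycle increase", call. = FALSE)
    }
    pct <- 100 * mean((records$treated_cycle - records$control_cycle) /
                        records$control_cycle)
  }
  out <- tibble::tibble(
    mean_delay = mean(diffs),
    sd_delay = if (length(diffs) > 1) stats::sd(diffs) else 0,
    n = length(diffs),
    percent_cycle_increase = pct
  )
  attr(out, "per_embryo") <- tibble::tibble(
    embryo = seq_along(diffs), difference = diffs)
  out
}

#' Power-normalised reporter-induction kinetics
#'
#' Divides per-embryo fluorescence time series by the imaging laser power
#' (so curves acquired at different powers are comparable) and averages
#' across embryos at each timepoint. Embryos imaged on slightly different
#' time grids are aligned to the first embryo's grid by nearest timepoint
#' within a tolerance; larger mismatches error.
#'
#' @param series A data frame with columns `embryo_id`, `time_h` and
#'   `fluorescence` (total counts).
#' @param laser_power Imaging laser power, uW: a single value, or a named
#'   vector/data frame (`embryo_id`, `laser_power`) per embryo. Positive.
#' @param align_tol Maximum timepoint mismatch absorbed by alignment, h.
#'   Default 0.05.
#' @return A tibble: `time_h`, `mean_intensity` (counts/uW), `sd`, `n`.
#' @export
kinetics_curve <- function(series, laser_power, align_tol = 0.05) {
  stopifnot(is.data.frame(series),
            all(c("embryo_id", "time_h", "fluorescence") %in% names(series)))
  series <- tibble::as_tibble(series)
  if (is.data.frame(laser_power)) {
    series <- dplyr::left_join(series, laser_power, by = "embryo_id")
  } else if (length(laser_power) == 1) {
    series$laser_power <- laser_power
  } else {
    series$laser_power <- unname(laser_power[as.character(series$embryo_id)])
  }
  if (any(is.na(series$laser_power) | series$laser_power <= 0)) {
    stop("laser power must be positive for every embryo", call. = FALSE)
  }
  grid <- sort(unique(series$time_h[series$embryo_id == series$embryo_id[1]]))
  snapped <- vapply(series$time_h, function(t) grid[which.min(abs(grid - t))], numeric(1))
  if (any(abs(snapped - series$time_h) > align_tol)) {
    stop(sprintf("time grids differ by more than the %g h alignment tolerance", align_tol),
         call. = FALSE)
  }
  series |>
    dplyr::mutate(time_h = snapped,
                  normalised = .data$fluorescence / .data$laser_power) |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(
      sd = if (dplyr::n() > 1) stats::sd(.data$normalised) else 0,
      n = dplyr::n(),
      mean_intensity = mean(.data$normalised),
      .groups = "drop"
    ) |>
    dplyr::select("time_h", "mean_intensity", "sd", "n")
}
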