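# Ratiometric fluorescence thermometry: calibrate the temperature sensitivity
# of a red reporter whose fluorescence falls linearly with temperature, then
# invert laser ON/OFF fluorescence ratios into temperature elevations, either
# per pixel (temperature maps) or per cell (ROI totals).
#
# Linear fluorescence law: F(T) = F_ref * (1 - s * (T - ref_temp)).
# ON/OFF ratio at base temperature T0 with elevation dT:
#   R = F(T0 + dT) / F(T0) = (1 - s (T0 + dT - ref)) / (1 - s (T0 - ref))
# inverted exactly as dT = (1 - R) * (1 - s (T0 - ref)) / s.

#' Fit the temperature sensitivity of a fluorescent reporter
#'
#' Normalises total-fluorescence measurements to the value at (or linearly
#' interpolated at) a reference temperature, fits an ordinary least-squares
#' line to normalised fluorescence versus temperature, and reports the
#' sensitivity as minus the slope: the fractional fluorescence decrease per
#' degC.
#'
#' @param data A data frame with columns `temperature` (degC) and
#'   `fluorescence` (background-subtracted total counts, positive).
#' @param ref_temp Normalisation anchor temperature, degC. Default 20.
#' @param valid_range Temperature validity window, degC. Default `c(15, 40)`.
#' @return An object of class `calibration_curve`: `sensitivity` (fraction per
#'   degC), `ref_temp`, `valid_range`, `fit_r_squared`, `n_points`, and the
#'   underlying `lm` fit. Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' d <- tibble::tibble(temperature = c(15, 20, 25, 30, 35, 40))
#' d$fluorescence <- 1000 * (1 - 0.017 * (d$temperature - 20))
#' fit_sensitivity(d)$sensitivity # 0.017
#' @export
fit_sensitivity <- function(data, ref_temp = 20, valid_range = c(15, 40)) {
  stopifnot(is.data.frame(data),
            all(c("temperature", "fluorescence") %in% names(data)))
  temp <- data$temperature
  fl <- data$fluorescence
  if (any(!is.finite(temp)) || any(!is.finite(fl))) {
    stop("non-finite calibration values", call. = FALSE)
  }
  if (any(fl <= 0)) stop("fluorescence must be positive", call. = FALSE)
  if (any(temp < valid_range[1] | temp > valid_range[2])) {
    stop(sprintf("temperatures outside the validity window [%g, %g] degC",
                 valid_range[1], valid_range[2]), call. = FALSE)
  }
  if (dplyr::n_distinct(temp) < 3) {
    stop("fit_sensitivity() needs >= 3 distinct temperatures", call. = FALSE)
  }
  f_ref <- if (any(temp == ref_temp)) {
    mean(fl[temp == ref_temp])
  } else {
    stats::approx(temp, fl, xout = ref_temp, ties = mean)$y
  }
  if (is.na(f_ref) || f_ref <= 0) {
    stop("cannot anchor normalisation: no usable fluorescence at ref_temp", call. = FALSE)
  }
  d <- tibble::tibble(temperature = temp, f_norm = fl / f_ref)
  fit <- stats::lm(f_norm ~ temperature, data = d)
  sm <- quiet_perfect_fit(summary(fit))
  structure(
    list(
      sensitivity = -unname(stats::coef(fit)["temperature"]),
      sensitivity_se = unname(sm$coefficients["temperature", "Std. Error"]),
      ref_temp = ref_temp,
      valid_range = valid_range,
      fit_r_squared = sm$r.squared,
      n_points = length(temp),
      fit = fit,
      data = d
    ),
    class = "calibration_curve"
  )
}

#' Construct a calibration curve from known constants
#'
#' Builds a `calibration_curve` directly from a known sensitivity (for
#' example the published 1.7%/degC value) without fitting.
#'
#' @param sensitivity Fractional fluorescence decrease per degC.
#' @param ref_temp Normalisation anchor, degC.
#' @param valid_range Validity window, degC.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(sensitivity = 0.017, ref_temp = 20,
                              valid_range = c(15, 40)) {
  stopifnot(sensitivity > 0, valid_range[1] < valid_range[2])
  structure(
    list(sensitivity = sensitivity, sensitivity_se = NA_real_,
         ref_temp = ref_temp, valid_range = valid_range,
         fit_r_squared = NA_real_, n_points = 0L, fit = NULL, data = NULL),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  sensitivity: %.4g per degC (%.3g%%/degC)\n",
              x$sensitivity, 100 * x$sensitivity))
  cat(sprintf("  ref temp: %g degC; valid range: [%g, %g] degC\n",
              x$ref_temp, x$valid_range[1], x$valid_range[2]))
  if (x$n_points > 0) {
    cat(sprintf("  fit: R^2 = %.5f over %d points\n", x$fit_r_squared, x$n_points))
  }
  invisible(x)
}

#' Total background-subtracted fluorescence in a cell ROI
#'
#' Sums pixel intensities over a cell region of interest and subtracts the
#' mean of a background ROI scaled by the cell pixel count:
#' `sum(cell) - mean(background) * n_cell`. A non-positive result (signal
#' indistinguishable from background) is returned with a warning.
#'
#' @param image A numeric matrix of counts.
#' @param cell_roi,background_roi Logical masks of the same dimension as
#'   `image`, or two-column matrices of (row, col) pixel indices. Must be
#'   non-empty and disjoint.
#' @return Total background-subtracted counts (scalar).
#' @export
quantify_cell_fluorescence <- function(image, cell_roi, background_roi) {
  stopifnot(is.matrix(image), is.numeric(image))
  cell_idx <- as_roi_index(cell_roi, dim(image), "cell_roi")
  bg_idx <- as_roi_index(background_roi, dim(image), "background_roi")
  if (length(cell_idx) == 0) stop("cell_roi is empty", call. = FALSE)
  if (length(bg_idx) == 0) stop("background_roi is empty", call. = FALSE)
  if (length(intersect(cell_idx, bg_idx)) > 0) {
    stop("cell_roi and background_roi overlap", call. = FALSE)
  }
  total <- sum(image[cell_idx]) - mean(image[bg_idx]) * length(cell_idx)
  if (total <= 0 && stats::var(image[cell_idx]) + stats::var(image[bg_idx]) > 0) {
    warning("cell signal is at or below background level", call. = FALSE)
  }
  total
}

# Noiseless synthetic data produce exact linear fits; summary.lm warns about
# them, which is expected here rather than suspicious.
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Normalise an ROI spec (logical mask or (row, col) index matrix) to linear
# pixel indices.
as_roi_index <- function(roi, dims, what) {
  if (is.logical(roi) && is.matrix(roi)) {
    if (!identical(dim(roi), dims)) {
      stop(sprintf("%s mask dimensions do not match the image", what), call. = FALSE)
    }
    return(which(roi))
  }
  if (is.matrix(roi) && ncol(roi) == 2) {
    if (any(roi[, 1] < 1 | roi[, 1] > dims[1] | roi[, 2] < 1 | roi[, 2] > dims[2])) {
      stop(sprintf("%s indices outside the image", what), call. = FALSE)
    }
    return((roi[, 2] - 1L) * dims[1] + roi[, 1])
  }
  stop(sprintf("%s must be a logical mask or a 2-column index matrix", what),
       call. = FALSE)
}

#' Invert a fluorescence ratio into a temperature elevation
#'
#' Exact inversion of the linear fluorescence law anchored at the base
#' temperature: `delta_t = (1 - R) * (1 - s * (base_temp - ref_temp)) / s`.
#' The naive approximation `delta_t = (1 - R) / s` (exact when
#' `base_temp == ref_temp`) is available via `anchored = FALSE`.
#'
#' @param ratio ON/OFF fluorescence ratio(s).
#' @param calibration A [calibration_curve()].
#' @param base_temp Temperature at which the OFF image was acquired, degC.
#' @param anchored Use the exact anchored inversion (default) or the naive
#'   approximation.
#' @return Temperature elevation(s), degC. Ratios above 1 give negative values.
#' @export
ratio_to_delta_t <- function(ratio, calibration, base_temp = calibration$ref_temp,
                             anchored = TRUE) {
  stopifnot(inherits(calibration, "calibration_curve"))
  s <- calibration$sensitivity
  if (s <= 0) stop("calibration sensitivity must be positive", call. = FALSE)
  if (anchored) {
    (1 - ratio) * (1 - s * (base_temp - calibration$ref_temp)) / s
  } else {
    (1 - ratio) / s
  }
}

# Non-overlapping block mean; trailing rows/cols that do not fill a block are
# dropped.
block_downsample <- function(image, factor) {
  stopifnot(is.matrix(image), factor >= 1, factor == as.integer(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  nr <- nrow(image) %/% factor
  nc <- ncol(image) %/% factor
  if (nr == 0 || nc == 0) stop("image smaller than one downsampling block", call. = FALSE)
  im <- image[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  arr <- array(im, dim = c(factor, nr, factor, nc))
  apply(arr, c(2, 4), mean)
}

# Background level estimator used when no background ROI is supplied: if a
# single exact value dominates (>5% of pixels, typical of synthetic or
# flat-field data) use it; otherwise take the modal bin midpoint of a
# Freedman-Diaconis histogram.
estimate_background <- function(image) {
  v <- as.vector(image)
  tab <- sort(table(v), decreasing = TRUE)
  if (tab[1] > 0.05 * length(v)) return(as.numeric(names(tab)[1]))
  h <- graphics::hist(v, breaks = "FD", plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Convert a laser ON/OFF image pair into a temperature-elevation map
#'
#' Both images are downsampled by a block mean (default 3x) to reduce noise
#' and background subtracted; the ON image is divided by the OFF image and the
#' ratio inverted through the calibrated linear fluorescence law anchored at
#' `base_temp`. Pixels whose background-subtracted OFF signal falls below a
#' validity floor (5 standard deviations of the background) are masked.
#'
#' @param on_image,off_image Numeric matrices of equal dimension (counts).
#' @param calibration A [calibration_curve()].
#' @param base_temp Ambient temperature of the OFF acquisition, degC; must lie
#'   within the calibration validity range.
#' @param downsample_factor Block size for the mean downsampling. Default 3.
#' @param background_roi Optional background ROI (mask or index matrix, at
#'   full resolution) used to estimate the background level and its standard
#'   deviation; when absent the modal intensity of the OFF image is used.
#' @param pixel_size Full-resolution pixel size, um/pixel. Default 1.
#' @param anchored Use the exact anchored ratio inversion. Default `TRUE`.
#' @return An object of class `temperature_map`: `delta_t` (matrix, degC, `NA`
#'   where masked), `mask` (logical matrix, `TRUE` = valid), `pixel_size`
#'   (um/pixel after downsampling), `downsample_factor`, `base_temp`. Supports
#'   [generics::tidy()] and [ggplot2::autoplot()].
#' @export
temperature_map <- function(on_image, off_image, calibration, base_temp,
                            downsample_factor = 3L, background_roi = NULL,
                            pixel_size = 1, anchored = TRUE) {
  stopifnot(is.matrix(on_image), is.matrix(off_image))
  if (!identical(dim(on_image), dim(off_image))) {
    stop("ON and OFF images must have identical dimensions", call. = FALSE)
  }
  stopifnot(inherits(calibration, "calibration_curve"))
  if (base_temp < calibration$valid_range[1] || base_temp > calibration$valid_range[2]) {
    stop(sprintf("base_temp %g degC outside calibration validity range [%g, %g]",
                 base_temp, calibration$valid_range[1], calibration$valid_range[2]),
         call. = FALSE)
  }
  if (is.null(background_roi)) {
    bg_on <- estimate_background(on_image)
    bg_off <- estimate_background(off_image)
    bg_sd <- 0
  } else {
    idx <- as_roi_index(background_roi, dim(off_image), "background_roi")
    bg_on <- mean(on_image[idx])
    bg_off <- mean(off_image[idx])
    bg_sd <- stats::sd(off_image[idx])
    if (is.na(bg_sd)) bg_sd <- 0
  }
  on_ds <- block_downsample(on_image - bg_on, downsample_factor)
  off_ds <- block_downsample(off_image - bg_off, downsample_factor)
  # downsampling averages the background sd down by the block size
  floor_val <- max(5 * bg_sd / downsample_factor, 1e-9 * max(abs(off_ds)))
  mask <- off_ds > floor_val
  ratio <- on_ds / off_ds
  delta_t <- ratio_to_delta_t(ratio, calibration, base_temp, anchored = anchored)
  delta_t[!mask] <- NA_real_
  structure(
    list(delta_t = delta_t, mask = mask,
         pixel_size = pixel_size * downsample_factor,
         downsample_factor = as.integer(downsample_factor),
         base_temp = base_temp),
    class = "temperature_map"
  )
}

#' @export
print.temperature_map <- function(x, ...) {
  cat("<temperature_map>\n")
  cat(sprintf("  grid: %d x %d at %.3g um/pixel (downsampled %dx)\n",
              nrow(x$delta_t), ncol(x$delta_t), x$pixel_size, x$downsample_factor))
  cat(sprintf("  base temperature: %g degC; valid pixels: %d/%d\n",
              x$base_temp, sum(x$mask), length(x$mask)))
  if (any(x$mask)) {
    cat(sprintf("  elevation range: [%.3g, %.3g] degC\n",
                min(x$delta_t, na.rm = TRUE), max(x$delta_t, na.rm = TRUE)))
  }
  invisible(x)
}

#' Per-cell temperature elevation from ON/OFF fluorescence totals
#'
#' Applies the same calibrated ratio inversion as [temperature_map()] to
#' scalar per-cell fluorescence totals. Ratios above 1 (apparent cooling,
#' expected only from noise) are returned as negative elevations flagged in
#' the `cooling_flag` column with a warning, not an error.
#'
#' @param measurements A data frame with columns `f_on` and `f_off`
#'   (background-subtracted totals; `f_off` must be positive). Additional
#'   columns (e.g. `cell_id`, `distance_to_focus`) pass through.
#' @param calibration A [calibration_curve()].
#' @param base_temp Ambient temperature of the OFF acquisition, degC.
#' @param anchored Use the exact anchored inversion. Default `TRUE`.
#' @return The input tibble with `ratio`, `delta_t` (degC) and `cooling_flag`
#'   columns appended.
#' @export
cell_delta_t <- function(measurements, calibration,
                         base_temp = calibration$ref_temp, anchored = TRUE) {
  stopifnot(is.data.frame(measurements),
            all(c("f_on", "f_off") %in% names(measurements)))
  if (any(measurements$f_off <= 0)) {
    stop("f_off must be positive for all measurements", call. = FALSE)
  }
  out <- tibble::as_tibble(measurements) |>
    dplyr::mutate(
      ratio = .data$f_on / .data$f_off,
      delta_t = ratio_to_delta_t(.data$ratio, calibration, base_temp,
                                 anchored = anchored),
      cooling_flag = .data$ratio > 1
    )
  if (any(out$cooling_flag)) {
    warning(sprintf("%d measurement(s) show apparent cooling (ON > OFF); returned as negative delta_t",
                    sum(out$cooling_flag)), call. = FALSE)
  }
  out
}

#' Bin per-cell temperature measurements by distance to the focus
#'
#' Groups measurements into half-open distance bins `[k w, (k+1) w)` and
#' reports the per-bin mean elevation, standard deviation and count. A bin
#' with a single measurement reports `sd = 0`.
#'
#' @param measurements A data frame with columns `distance_to_focus` (um) and
#'   `delta_t` (degC); a `power` column, when present, is kept as a grouping
#'   variable so profiles at several powers can be binned in one call.
#' @param bin_width Bin width, um. Default 2.
#' @return A tibble with columns (`power`,) `bin`, `distance` (bin centre,
#'   um), `delta_t` (mean, degC), `sd`, `n`.
#' @export
bin_by_distance <- function(measurements, bin_width = 2) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1,
            all(c("distance_to_focus", "delta_t") %in% names(measurements)),
            bin_width > 0)
  grouping <- if ("power" %in% names(measurements)) c("power", "bin") else "bin"
  tibble::as_tibble(measurements) |>
    dplyr::mutate(bin = floor(.data$distance_to_focus / bin_width)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      distance = (.data$bin[1] + 0.5) * bin_width,
      sd = if (dplyr::n() > 1) stats::sd(.data$delta_t) else 0,
      n = dplyr::n(),
      delta_t = mean(.data$delta_t),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(setdiff(grouping, "bin")), "bin", "distance",
                  "delta_t", "sd", "n") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grouping)))
  }
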