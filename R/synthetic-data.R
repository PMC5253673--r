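# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth: calibration image series of a
# temperature-sensitive reporter, laser ON/OFF image pairs over a point
# heat source with exponential spatial decay, per-cell temperature
# measurement tables, elongating neurite tracks, and paired left/right
# division-timing records.
#
# Scene model: a thin sheet of reporter-expressing cells rendered as
# uniform-intensity discs with a 1-pixel Gaussian-softened edge on a flat
# background. Fluorescence follows F(T) = F0 * (1 - s * (T - ref_temp)).
# Noise is Poisson shot noise on the expected counts plus Gaussian read
# noise. All generators are bit-reproducible under a fixed seed.

#' Specify a synthetic imaging scene
#'
#' @param image_shape Image size in pixels, `c(rows, cols)`.
#' @param pixel_size Pixel size, um/pixel.
#' @param cell_centers Cell centre positions in um, a two-column matrix or
#'   data frame with columns `x`, `y`. Default: one cell at the image centre.
#' @param cell_radius Cell radius, um.
#' @param base_fluorescence Per-pixel cell counts at the reference
#'   temperature. Must exceed `background_level`.
#' @param background_level Flat background, counts. Non-negative.
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param shot_noise Apply Poisson shot noise?
#' @param seed Integer seed used by the image generators.
#' @return An object of class `scene_spec`.
#' @details The defaults (0.2 um pixels, 2.5 um cell radius, 200 counts per
#'   cell pixel over a background of 10) give per-cell totals of order 1e5
#'   counts, for which the shot-noise-limited per-cell temperature error of
#'   the ratiometric readout is about 0.3 degC at 1.7%/degC sensitivity.
#' @export
scene_spec <- function(image_shape = c(192L, 192L), pixel_size = 0.2,
                       cell_centers = NULL, cell_radius = 2.5,
                       base_fluorescence = 200, background_level = 10,
                       read_noise_sd = 2, shot_noise = TRUE, seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  stopifnot(pixel_size > 0, cell_radius > 0)
  stopifnot(background_level >= 0, base_fluorescence > background_level)
  stopifnot(read_noise_sd >= 0)
  if (is.null(cell_centers)) {
    cell_centers <- matrix(rev(image_shape) / 2 * pixel_size, ncol = 2)
    colnames(cell_centers) <- c("x", "y")
  }
  cell_centers <- as.matrix(as.data.frame(cell_centers)[, c("x", "y")])
  extent <- rev(image_shape) * pixel_size
  if (any(cell_centers[, 1] < 0 | cell_centers[, 1] > extent[1] |
          cell_centers[, 2] < 0 | cell_centers[, 2] > extent[2])) {
    stop("cell centre outside the image", call. = FALSE)
  }
  structure(
    list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
         cell_centers = cell_centers, cell_radius = cell_radius,
         base_fluorescence = base_fluorescence,
         background_level = background_level,
         read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d x %d px at %g um/px, %d cell(s), base %g over background %g counts\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size,
              nrow(x$cell_centers), x$base_fluorescence, x$background_level))
  invisible(x)
}

# um coordinates of pixel centres (0-based pixel k spans [k, k+1) * pixel_size)
pixel_coords <- function(spec) {
  list(
    x = (seq_len(spec$image_shape[2]) - 0.5) * spec$pixel_size,
    y = (seq_len(spec$image_shape[1]) - 0.5) * spec$pixel_size
  )
}

# Soft-edged disc occupancy in [0, 1] per pixel for one cell centre.
# Edge softening: Gaussian with sigma of one pixel.
disc_occupancy <- function(spec, center) {
  co <- pixel_coords(spec)
  dx <- outer(rep(1, spec$image_shape[1]), co$x - center[1])
  dy <- outer(co$y - center[2], rep(1, spec$image_shape[2]))
  d <- sqrt(dx^2 + dy^2)
  stats::pnorm((spec$cell_radius - d) / spec$pixel_size)
}

# Expected (noiseless) image for a per-pixel temperature field (scalar or
# matrix, degC). Cell pixels follow the linear fluorescence law; the
# background is temperature independent.
render_scene <- function(spec, temperature, sensitivity, ref_temp) {
  scale <- 1 - sensitivity * (temperature - ref_temp)
  if (any(scale < 0)) {
    stop("negative scaled fluorescence: sensitivity x temperature range too large",
         call. = FALSE)
  }
  occ <- Reduce(`+`, lapply(seq_len(nrow(spec$cell_centers)), function(i) {
    disc_occupancy(spec, spec$cell_centers[i, ])
  }))
  occ <- pmin(occ, 1)
  spec$background_level + spec$base_fluorescence * occ * scale
}

# Poisson shot noise + Gaussian read noise, clipped at zero (counts are
# non-negative). Uses the current RNG state; callers fix the seed.
apply_noise <- function(expected, spec) {
  img <- expected
  if (spec$shot_noise) {
    img[] <- stats::rpois(length(img), lambda = pmax(expected, 0))
  }
  if (spec$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = spec$read_noise_sd)
  }
  pmax(img, 0)
}

#' Cell and background ROI masks for a synthetic scene
#'
#' @param spec A [scene_spec()].
#' @param cell Index of the cell (row of `cell_centers`).
#' @param pad Padding added to the cell radius, um, so the ROI captures the
#'   softened edge. Default 3 pixels.
#' @return A logical mask matrix.
#' @export
cell_roi_mask <- function(spec, cell = 1L, pad = 3 * spec$pixel_size) {
  co <- pixel_coords(spec)
  center <- spec$cell_centers[cell, ]
  dx <- outer(rep(1, spec$image_shape[1]), co$x - center[1])
  dy <- outer(co$y - center[2], rep(1, spec$image_shape[2]))
  sqrt(dx^2 + dy^2) <= spec$cell_radius + pad
}

#' @rdname cell_roi_mask
#' @param margin Distance beyond any cell that background pixels must keep,
#'   um. Default 5 pixels beyond the ROI padding.
#' @export
background_roi_mask <- function(spec, margin = 8 * spec$pixel_size) {
  near_any <- Reduce(`|`, lapply(seq_len(nrow(spec$cell_centers)), function(i) {
    cell_roi_mask(spec, i, pad = margin)
  }))
  !near_any
}

#' Generate a temperature-calibration image series
#'
#' Renders the scene at each bath temperature with cell fluorescence scaled by
#' the linear law `1 - sensitivity * (T - ref_temp)`; the background is
#' unaffected by temperature. Noise per [scene_spec()].
#'
#' @param spec A [scene_spec()].
#' @param sensitivity Fractional fluorescence decrease per degC, in (0, 0.1).
#' @param temperatures Bath temperatures, degC, all inside `valid_range`.
#' @param ref_temp Reference temperature, degC. Default 20.
#' @param valid_range Temperature validity window. Default `c(15, 40)`.
#' @return A list: `images` (named list of matrices, one per temperature),
#'   `table` (tibble `temperature`, `expected_total` of noiseless
#'   background-subtracted cell counts summed over all cells), `truth`
#'   (generating parameters), `spec`.
#' @export
gen_calibration_series <- function(spec, sensitivity = 0.017, temperatures,
                                   ref_temp = 20, valid_range = c(15, 40)) {
  stopifnot(inherits(spec, "scene_spec"))
  if (sensitivity <= 0 || sensitivity >= 0.1) {
    stop("sensitivity must lie in (0, 0.1)", call. = FALSE)
  }
  if (any(temperatures < valid_range[1] | temperatures > valid_range[2])) {
    stop(sprintf("temperatures outside the validity window [%g, %g] degC",
                 valid_range[1], valid_range[2]), call. = FALSE)
  }
  occ_total <- sum(pmin(Reduce(`+`, lapply(seq_len(nrow(spec$cell_centers)),
    function(i) disc_occupancy(spec, spec$cell_centers[i, ]))), 1))
  images <- withr::with_seed(spec$seed, {
    lapply(temperatures, function(tt) {
      apply_noise(render_scene(spec, tt, sensitivity, ref_temp), spec)
    })
  })
  names(images) <- sprintf("T%g", temperatures)
  tbl <- tibble::tibble(
    temperature = temperatures,
    expected_total = spec$base_fluorescence * occ_total *
      (1 - sensitivity * (temperatures - ref_temp))
  )
  list(images = images, table = tbl,
       truth = list(sensitivity = sensitivity, ref_temp = ref_temp,
                    valid_range = valid_range),
       spec = spec)
}

#' Generate a laser ON/OFF image pair over a point heat source
#'
#' The OFF image is rendered at the ambient temperature of `profile`; the ON
#' image at `ambient + slope * power * 2^(-r/half_distance)` per pixel, where
#' `r` is the in-plane distance to the laser focus. The full-resolution truth
#' elevation map is returned alongside.
#'
#' @param spec A [scene_spec()].
#' @param profile A [thermal_profile()].
#' @param focus Laser focus position `c(x, y)` in um, inside the image.
#' @param power Laser power, mW. Non-negative.
#' @param sensitivity Fractional fluorescence decrease per degC.
#' @param ref_temp Reference temperature of the fluorescence law, degC.
#'   Default: the profile ambient, so the OFF image equals the base scene.
#' @return A list: `on`, `off` (matrices), `truth_delta_t` (full-resolution
#'   elevation matrix, degC), `truth` (parameters), `spec`.
#' @export
gen_onoff_pair <- function(spec, profile, focus, power, sensitivity = 0.017,
                           ref_temp = profile$ambient) {
  stopifnot(inherits(spec, "scene_spec"), inherits(profile, "thermal_profile"))
  if (power < 0) stop("power must be non-negative", call. = FALSE)
  extent <- rev(spec$image_shape) * spec$pixel_size
  if (focus[1] < 0 || focus[1] > extent[1] || focus[2] < 0 || focus[2] > extent[2]) {
    stop("laser focus outside the image", call. = FALSE)
  }
  co <- pixel_coords(spec)
  dx <- outer(rep(1, spec$image_shape[1]), co$x - focus[1])
  dy <- outer(co$y - focus[2], rep(1, spec$image_shape[2]))
  r <- sqrt(dx^2 + dy^2)
  truth_delta_t <- profile$slope * power * 2^(-r / profile$half_distance)
  pair <- withr::with_seed(spec$seed, {
    off <- apply_noise(render_scene(spec, profile$ambient, sensitivity, ref_temp), spec)
    on <- apply_noise(render_scene(spec, profile$ambient + truth_delta_t,
                                   sensitivity, ref_temp), spec)
    list(on = on, off = off)
  })
  list(on = pair$on, off = pair$off, truth_delta_t = truth_delta_t,
       truth = list(sensitivity = sensitivity, ref_temp = ref_temp,
                    power = power, focus = focus, profile = profile),
       spec = spec)
}

#' Generate a per-cell temperature measurement table
#'
#' Each row is one cell at a known distance from the laser focus, with the
#' true elevation from the exponential-decay heating model plus Gaussian
#' measurement noise.
#'
#' @param profile A [thermal_profile()].
#' @param powers Laser powers, mW.
#' @param cell_distances Distances to the focus, um (recycled across powers).
#' @param noise_sd Gaussian noise sd on the elevation, degC. Non-negative.
#' @param seed Integer seed.
#' @return A tibble: `power`, `cell_id`, `distance_to_focus`, `delta_t_true`,
#'   `delta_t` (noisy, degC).
#' @export
gen_cell_measurements <- function(profile, powers, cell_distances,
                                  noise_sd = 0.3, seed = 1L) {
  stopifnot(inherits(profile, "thermal_profile"), noise_sd >= 0)
  if (length(cell_distances) == 0) stop("cell_distances is empty", call. = FALSE)
  if (any(cell_distances < 0)) stop("distances must be non-negative", call. = FALSE)
  tbl <- tidyr::expand_grid(power = powers,
                            distance_to_focus = cell_distances) |>
    dplyr::mutate(
      cell_id = dplyr::row_number(),
      delta_t_true = predict_profile(.data$power, .data$distance_to_focus, profile)
    )
  withr::with_seed(as.integer(seed), {
    tbl$delta_t <- tbl$delta_t_true + stats::rnorm(nrow(tbl), sd = noise_sd)
  })
  tbl[, c("power", "cell_id", "distance_to_focus", "delta_t_true", "delta_t")]
}

#' Generate an elongating neurite track series
#'
#' Produces an ordered 3D point list per timepoint whose polyline length
#' follows a piecewise-linear growth schedule: zero before the onset stage,
#' then increasing at `rate` um per unit stage. Without jitter, the polyline
#' length equals the scheduled length exactly.
#'
#' @param stages Developmental stages, ascending, in `[0, 1]`.
#' @param growth_onset_stage Stage at which outgrowth begins.
#' @param rate Growth rate, um per unit stage.
#' @param jitter_sd Per-point Gaussian jitter sd, um. Default 0 (off).
#' @param seed Integer seed.
#' @param step Target spacing between consecutive points, um. Default 1.
#' @return A tibble: `time` (= stage index), `stage`, `point_index`, `x`, `y`,
#'   `z` (um); one row per annotated point.
#' @export
gen_neurite_tracks <- function(stages, growth_onset_stage, rate,
                               jitter_sd = 0, seed = 1L, step = 1) {
  stopifnot(all(stages >= 0 & stages <= 1), !is.unsorted(stages), rate >= 0,
            jitter_sd >= 0, step > 0)
  withr::with_seed(as.integer(seed), {
    # fixed gently-curving 3D direction sequence, shared across timepoints so
    # that tracks at successive stages extend the same path
    max_len <- max(rate * (max(stages) - growth_onset_stage), 0)
    n_max <- max(ceiling(max_len / step), 1) + 1
    ang <- cumsum(c(0, stats::runif(n_max, -0.2, 0.2)))
    elev <- cumsum(c(0, stats::runif(n_max, -0.1, 0.1)))
    dirs <- cbind(cos(ang) * cos(elev), sin(ang) * cos(elev), sin(elev))
    purrr::imap_dfr(stages, function(st, i) {
      len <- max(rate * (st - growth_onset_stage), 0)
      if (len == 0) {
        pts <- matrix(0, nrow = 1, ncol = 3)
      } else {
        n_seg <- max(ceiling(len / step), 1)
        seg <- dirs[seq_len(n_seg), , drop = FALSE] * (len / n_seg)
        pts <- rbind(0, apply(seg, 2, cumsum))
        if (jitter_sd > 0) {
          pts <- pts + matrix(stats::rnorm(length(pts), sd = jitter_sd),
                              ncol = 3)
        }
      }
      tibble::tibble(time = i, stage = st,
                     point_index = seq_len(nrow(pts)),
                     x = pts[, 1], y = pts[, 2], z = pts[, 3])
    })
  })
}

#' Generate paired left/right division-timing records
#'
#' Each embryo contributes a heated-side and a control-side terminal division
#' time whose difference is `mean_delay` plus Gaussian noise of sd
#' `natural_sd` (the natural left/right timing variability). Optional cycle
#' columns carry parent-to-division intervals so percent cycle-time increases
#' can be computed; the control cycle defaults to 63 min so a 17 min delay
#' corresponds to a ~27% cycle increase.
#'
#' @param n_embryos Number of embryos, >= 1.
#' @param mean_delay Mean heated-minus-control delay, min.
#' @param natural_sd Natural left/right timing sd, min. Non-negative.
#' @param seed Integer seed.
#' @param base_time Mean absolute division time, min.
#' @param base_sd Between-embryo sd of the absolute division time, min.
#' @param control_cycle Control-side cell-cycle length, min.
#' @param include_cycles Append `treated_cycle`/`control_cycle` columns?
#' @return A tibble: `embryo_id`, `treated_time`, `control_time` (min), and
#'   optionally `treated_cycle`, `control_cycle` (min).
#' @export
gen_division_timings <- function(n_embryos, mean_delay, natural_sd, seed = 1L,
                                 base_time = 200, base_sd = 8,
                                 control_cycle = 63, include_cycles = TRUE) {
  stopifnot(n_embryos >= 1, natural_sd >= 0)
  withr::with_seed(as.integer(seed), {
    control <- base_time + stats::rnorm(n_embryos, sd = base_sd)
    diff <- mean_delay + stats::rnorm(n_embryos, sd = natural_sd)
    out <- tibble::tibble(
      embryo_id = seq_len(n_embryos),
      treated_time = control + diff,
      control_time = control
    )
    if (include_cycles) {
      out$control_cycle <- rep(control_cycle, n_embryos)
      out$treated_cycle <- control_cycle + diff
    }
    out
  })
}
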