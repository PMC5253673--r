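# Formats, configuration and the pipeline driver. Images travel as multi-page
# TIFF with a YAML sidecar carrying pixel size and the intensity scale (TIFF
# float storage is confined to [0, 1], so counts are scaled on write and
# restored on read); tables as CSV; configs, profiles and manifests as YAML.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a multi-page image stack as TIFF with metadata sidecar
#'
#' Intensities are scaled into `[0, 1]` by a single scale factor (recorded in
#' the sidecar together with the pixel size and any extra provenance fields)
#' and stored as 32-bit float, exact to float32 precision (~1e-7 relative).
#'
#' @param images A matrix or list of matrices (counts).
#' @param path Output TIFF path.
#' @param pixel_size Pixel size, um/pixel.
#' @param metadata Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(images, path, pixel_size, metadata = list()) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(all(vapply(images, is.matrix, logical(1))), pixel_size > 0)
  scale <- max(1, vapply(images, max, numeric(1)))
  tiff::writeTIFF(lapply(images, function(m) m / scale), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  yaml::write_yaml(
    c(list(pixel_size_um = pixel_size, intensity_scale = scale,
           n_pages = length(images)), metadata),
    sidecar_path(path))
  invisible(path)
}

#' Read a multi-page image stack with pixel-size metadata
#'
#' Reads a single- or multi-page TIFF. Pixel size and intensity scale are
#' taken from the YAML sidecar written by [write_image_stack()]; when the
#' sidecar is absent, `default_pixel_size` is used with a warning (and
#' intensities are returned as stored).
#'
#' @param path TIFF path.
#' @param default_pixel_size Fallback pixel size, um/pixel, used (with a
#'   warning) when no sidecar metadata exists.
#' @return A list of class `image_stack`: `images` (list of matrices),
#'   `pixel_size`, `metadata`.
#' @export
load_image_stack <- function(path, default_pixel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = FALSE),
    error = function(e) {
      stop(sprintf("cannot read '%s' as TIFF: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (is.matrix(pages)) pages <- list(pages)
  meta <- list()
  if (file.exists(sidecar_path(path))) {
    meta <- yaml::read_yaml(sidecar_path(path))
  }
  pixel_size <- meta$pixel_size_um
  if (is.null(pixel_size)) {
    if (is.null(default_pixel_size)) {
      stop(sprintf("no pixel-size metadata for '%s' and no default supplied", path),
           call. = FALSE)
    }
    warning(sprintf("no pixel-size metadata for '%s'; using default %g um/pixel",
                    path, default_pixel_size), call. = FALSE)
    pixel_size <- default_pixel_size
  }
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  images <- lapply(pages, function(m) m * scale)
  structure(list(images = images, pixel_size = pixel_size, metadata = meta),
            class = "image_stack")
}

#' Serialise and restore a thermal profile
#'
#' Profiles travel as YAML with explicit units in the field names.
#'
#' @param profile A [thermal_profile()].
#' @param path Output path.
#' @return `path` invisibly; `read_thermal_profile()` returns the profile.
#' @export
write_thermal_profile <- function(profile, path) {
  stopifnot(inherits(profile, "thermal_profile"))
  yaml::write_yaml(list(
    slope_c_per_mw = profile$slope,
    half_distance_um = profile$half_distance,
    ambient_c = profile$ambient,
    tau_ms = profile$tau
  ), path)
  invisible(path)
}

#' @rdname write_thermal_profile
#' @export
read_thermal_profile <- function(path) {
  f <- yaml::read_yaml(path)
  thermal_profile(slope = f$slope_c_per_mw, half_distance = f$half_distance_um,
                  ambient = f$ambient_c, tau = f$tau_ms)
}

#' Pipeline configuration
#'
#' A single structured configuration for the synthetic end-to-end pipeline,
#' with explicit units in the field names to prevent unit drift. The seed is
#' mandatory: every stochastic step derives from it.
#'
#' @param seed Integer seed (mandatory).
#' @param ref_temp_c Calibration reference temperature, degC.
#' @param valid_range_c Calibration validity window, degC.
#' @param slope_c_per_mw,half_distance_um,ambient_c,tau_ms Heating-model
#'   constants used by the generator.
#' @param calib_temperatures_c Bath temperatures for the calibration series.
#' @param sensitivity_per_c Generating reporter sensitivity, fraction/degC.
#' @param map_power_mw Laser power for the ON/OFF pair, mW.
#' @param measure_powers_mw Powers for the per-cell measurement table, mW.
#' @param n_cells_per_power Cells per power in the measurement table.
#' @param max_distance_um Largest cell distance sampled, um.
#' @param measure_noise_sd_c Per-cell measurement noise sd, degC.
#' @param band_c Heat-shock band, degC.
#' @param lethal_temp_c Ablation lethal temperature, degC.
#' @param neighbor_distance_um Nearest-neighbour distance for planning, um.
#' @param downsample_factor Temperature-map downsampling block size.
#' @param scene A [scene_spec()]; default built from the seed.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed,
                            ref_temp_c = 20, valid_range_c = c(15, 40),
                            slope_c_per_mw = 4, half_distance_um = 11,
                            ambient_c = 20, tau_ms = 500 / log(20),
                            calib_temperatures_c = seq(15, 40, by = 2.5),
                            sensitivity_per_c = 0.017,
                            map_power_mw = 3.5,
                            measure_powers_mw = c(2, 3, 4),
                            n_cells_per_power = 40,
                            max_distance_um = 35,
                            measure_noise_sd_c = 0.3,
                            band_c = c(32, 34), lethal_temp_c = 50,
                            neighbor_distance_um = 11,
                            downsample_factor = 3L,
                            scene = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  if (is.null(scene)) scene <- scene_spec(seed = seed)
  cfg <- list(
    seed = seed, ref_temp_c = ref_temp_c, valid_range_c = valid_range_c,
    slope_c_per_mw = slope_c_per_mw, half_distance_um = half_distance_um,
    ambient_c = ambient_c, tau_ms = tau_ms,
    calib_temperatures_c = calib_temperatures_c,
    sensitivity_per_c = sensitivity_per_c, map_power_mw = map_power_mw,
    measure_powers_mw = measure_powers_mw,
    n_cells_per_power = n_cells_per_power,
    max_distance_um = max_distance_um,
    measure_noise_sd_c = measure_noise_sd_c,
    band_c = band_c, lethal_temp_c = lethal_temp_c,
    neighbor_distance_um = neighbor_distance_um,
    downsample_factor = as.integer(downsample_factor),
    scene = scene
  )
  structure(cfg, class = "pipeline_config")
}

pipeline_stage_deps <- c(simulate = "", calibrate = "simulate",
                         map = "calibrate", fit = "simulate", plan = "fit")

# Content hash of a stage result that is stable across sessions: model
# objects (lm/nls) carry environments whose serialisation is not
# reproducible, so they are reduced to coefficients and fitted values.
stage_digest <- function(x) {
  canon <- function(v) {
    if (inherits(v, "lm") || inherits(v, "nls")) {
      return(list(coef = stats::coef(v), fitted = as.numeric(stats::fitted(v))))
    }
    if (is.environment(v) || is.function(v)) return(NULL)
    if (is.list(v)) return(lapply(unclass(v), canon))
    v
  }
  rlang::hash(canon(x))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes an ordered subset of the stages `simulate` (generate all synthetic
#' inputs), `calibrate` (ROI quantification and sensitivity fit), `map`
#' (ON/OFF temperature map), `fit` (power slope and joint spatial-decay fit)
#' and `plan` (induction plan from the fitted profile). Stage dependencies
#' are checked; a missing upstream stage errors naming it. Deterministic
#' given the config (which carries the seed): the manifest records a content
#' hash per stage.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run, in order. Default: all.
#' @return A list of class `pipeline_run`: one element per executed stage
#'   plus `manifest`, a tibble (`stage`, `params`, `digest`).
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "calibrate", "map", "fit", "plan")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, names(pipeline_stage_deps), several.ok = TRUE)
  done <- character()
  out <- list()
  manifest <- list()
  profile_true <- thermal_profile(slope = config$slope_c_per_mw,
                                  half_distance = config$half_distance_um,
                                  ambient = config$ambient_c,
                                  tau = config$tau_ms)
  for (st in stages) {
    dep <- pipeline_stage_deps[[st]]
    if (nzchar(dep) && !dep %in% done) {
      stop(sprintf("stage '%s' requires upstream stage '%s'", st, dep),
           call. = FALSE)
    }
    res <- switch(st,
      simulate = {
        scene <- config$scene
        calib <- gen_calibration_series(scene, config$sensitivity_per_c,
                                        config$calib_temperatures_c,
                                        ref_temp = config$ref_temp_c,
                                        valid_range = config$valid_range_c)
        extent <- rev(scene$image_shape) * scene$pixel_size
        pair <- gen_onoff_pair(scene, profile_true, focus = extent / 2,
                               power = config$map_power_mw,
                               sensitivity = config$sensitivity_per_c,
                               ref_temp = config$ambient_c)
        distances <- withr::with_seed(config$seed, {
          stats::runif(config$n_cells_per_power, 0, config$max_distance_um)
        })
        cells <- gen_cell_measurements(profile_true, config$measure_powers_mw,
                                       distances,
                                       noise_sd = config$measure_noise_sd_c,
                                       seed = config$seed)
        list(calibration_series = calib, onoff = pair, cell_measurements = cells)
      },
      calibrate = {
        sim <- out$simulate
        roi <- cell_roi_mask(config$scene)
        bg <- background_roi_mask(config$scene)
        tbl <- tibble::tibble(
          temperature = sim$calibration_series$table$temperature,
          fluorescence = vapply(sim$calibration_series$images,
                                quantify_cell_fluorescence, numeric(1),
                                cell_roi = roi, background_roi = bg)
        )
        fit_sensitivity(tbl, ref_temp = config$ref_temp_c,
                        valid_range = config$valid_range_c)
      },
      map = {
        sim <- out$simulate
        temperature_map(sim$onoff$on, sim$onoff$off, out$calibrate,
                        base_temp = config$ambient_c,
                        downsample_factor = config$downsample_factor,
                        background_roi = background_roi_mask(config$scene),
                        pixel_size = config$scene$pixel_size)
      },
      fit = {
        sim <- out$simulate
        binned <- bin_by_distance(sim$cell_measurements, bin_width = 2)
        spatial <- fit_spatial_profile(binned, profile = profile_true)
        focal <- sim$cell_measurements |>
          dplyr::filter(.data$distance_to_focus < 2) |>
          dplyr::transmute(.data$power,
                           temperature = config$ambient_c + .data$delta_t)
        slope_fit <- if (dplyr::n_distinct(focal$power) >= 2) {
          fit_power_slope(focal, ambient = config$ambient_c)
        } else NULL
        list(spatial = spatial, slope = slope_fit,
             profile = spatial$profile)
      },
      plan = {
        plan_induction(out$fit$profile, threshold_band = config$band_c,
                       neighbor_distance = config$neighbor_distance_um,
                       ambient = config$ambient_c)
      }
    )
    out[[st]] <- res
    manifest[[st]] <- tibble::tibble(
      stage = st,
      params = paste0("seed=", config$seed),
      digest = stage_digest(res)
    )
    done <- c(done, st)
  }
  out$manifest <- dplyr::bind_rows(manifest)
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$manifest)
  invisible(x)
}
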