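# Calibration fitting, ROI quantification, ratio inversion, temperature maps
# and distance binning.

test_that("fit_sensitivity recovers the generating sensitivity on noiseless data", {
  d <- tibble::tibble(temperature = seq(15, 40, 2.5))
  d$fluorescence <- 1000 * (1 - 0.017 * (d$temperature - 20))
  fit <- fit_sensitivity(d, ref_temp = 20)
  expect_equal(fit$sensitivity, 0.017, tolerance = 1e-9)
  expect_equal(fit$fit_r_squared, 1, tolerance = 1e-9)
  expect_identical(fit$n_points, nrow(d))
})

test_that("fit_sensitivity handles constant fluorescence and hand-checkable slopes", {
  d <- tibble::tibble(temperature = c(20, 30, 40), fluorescence = 500)
  expect_equal(fit_sensitivity(d)$sensitivity, 0, tolerance = 1e-12)
  # hand formula: three exact points on F = 1 - 0.02 (T - 20), slope -0.02
  d2 <- tibble::tibble(temperature = c(20, 30, 40),
                       fluorescence = 800 * c(1, 0.8, 0.6))
  expect_equal(fit_sensitivity(d2)$sensitivity, 0.02, tolerance = 1e-12)
})

test_that("fit_sensitivity rejects degenerate and invalid inputs", {
  expect_error(fit_sensitivity(tibble::tibble(temperature = c(20, 20, 20),
                                              fluorescence = c(1, 2, 3))),
               "distinct temperatures")
  expect_error(fit_sensitivity(tibble::tibble(temperature = c(20, 25, 30),
                                              fluorescence = c(1, -2, 3))),
               "positive")
  expect_error(fit_sensitivity(tibble::tibble(temperature = c(5, 25, 30),
                                              fluorescence = c(1, 2, 3))),
               "validity window")
})

test_that("fit_sensitivity is invariant to uniform rescaling of fluorescence", {
  withr::with_seed(10, {
    d <- tibble::tibble(temperature = seq(15, 40, 5))
    d$fluorescence <- 2000 * (1 - 0.017 * (d$temperature - 20)) * exp(rnorm(6, sd = 0.004))
    for (k in c(0.01, 1, 370)) {
      d2 <- dplyr::mutate(d, fluorescence = fluorescence * k)
      expect_equal(fit_sensitivity(d2)$sensitivity, fit_sensitivity(d)$sensitivity,
                   tolerance = 1e-12)
    }
  })
})

test_that("quantify_cell_fluorescence subtracts background over the cell area", {
  img <- matrix(10, 20, 20)
  img[5:9, 5:9] <- 100
  cell <- matrix(FALSE, 20, 20); cell[5:9, 5:9] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[15:19, 15:19] <- TRUE
  expect_equal(quantify_cell_fluorescence(img, cell, bg), (100 - 10) * 25)
  # uniform image: zero signal, flagged
  flat <- matrix(10, 20, 20)
  expect_equal(quantify_cell_fluorescence(flat, cell, bg), 0)
  expect_error(quantify_cell_fluorescence(img, cell, cell), "overlap")
  empty <- matrix(FALSE, 20, 20)
  expect_error(quantify_cell_fluorescence(img, cell, empty), "empty")
})

test_that("ratio inversion round-trips elevations to machine precision", {
  cal20 <- calibration_curve(ref_temp = 20)
  for (s in c(0.006, 0.017, 0.049)) {
    for (dt in c(0, 0.5, 5, 14, 25)) {
      for (base in c(18, 20, 24)) {
        cal <- calibration_curve(sensitivity = s, ref_temp = 20)
        f_base <- 1 - s * (base - 20)
        ratio <- (1 - s * (base + dt - 20)) / f_base
        m <- tibble::tibble(f_on = 1000 * ratio, f_off = 1000)
        out <- cell_delta_t(m, cal, base_temp = base)
        expect_equal(out$delta_t, dt, tolerance = 1e-9)
      }
    }
  }
  # documented naive approximation agrees only at the anchor
  expect_equal(ratio_to_delta_t(0.83, cal20, 20, anchored = FALSE),
               ratio_to_delta_t(0.83, cal20, 20, anchored = TRUE))
})

test_that("cell_delta_t reproduces worked examples and flags apparent cooling", {
  cal <- calibration_curve(sensitivity = 0.017, ref_temp = 20)
  m <- tibble::tibble(f_on = c(1000, 915, 1017), f_off = 1000)
  expect_warning(out <- cell_delta_t(m, cal, base_temp = 20), "cooling")
  expect_equal(out$delta_t[1], 0)
  expect_equal(out$delta_t[2], 5.0, tolerance = 1e-9)
  expect_equal(out$delta_t[3], -1, tolerance = 1e-9)
  expect_identical(out$cooling_flag, c(FALSE, FALSE, TRUE))
  expect_error(cell_delta_t(tibble::tibble(f_on = 1, f_off = 0), cal), "positive")
})

test_that("larger fluorescence decrease implies larger inferred elevation", {
  cal <- calibration_curve(0.017, 20)
  ratios <- seq(0.99, 0.5, by = -0.01)
  dts <- ratio_to_delta_t(ratios, cal, base_temp = 22)
  expect_true(all(diff(dts) > 0))
})

test_that("temperature_map inverts a noiseless ON/OFF pair and masks background", {
  sc <- noiseless_scene()
  prof <- ref_profile()
  cal <- calibration_curve(0.017, ref_temp = 20)
  pr <- gen_onoff_pair(sc, prof, focus = c(19.2, 19.2), power = 3.5)
  bg <- background_roi_mask(sc)
  tm <- temperature_map(pr$on, pr$off, cal, base_temp = 20,
                        background_roi = bg, pixel_size = sc$pixel_size)
  truth <- lasertherm:::block_downsample(pr$truth_delta_t, 3)
  interior <- erode_mask(tm$mask, 4)
  expect_gt(sum(interior), 5)
  expect_lt(max(abs(tm$delta_t - truth)[interior]), 0.05)
  expect_equal(max(tm$delta_t, na.rm = TRUE), 14, tolerance = 0.5)
  # background is masked
  expect_true(all(is.na(tm$delta_t[!tm$mask])))
  # identical images: all-zero unmasked map
  tm0 <- temperature_map(pr$off, pr$off, cal, base_temp = 20, background_roi = bg)
  expect_equal(max(abs(tm0$delta_t), na.rm = TRUE), 0)
})

test_that("temperature_map validates its inputs", {
  cal <- calibration_curve()
  a <- matrix(1, 9, 9); b <- matrix(1, 12, 9)
  expect_error(temperature_map(a, b, cal, 20), "identical dimensions")
  expect_error(temperature_map(a, a, cal, 50), "validity range")
})

test_that("bin_by_distance uses half-open bins and single-member sd of 0", {
  m <- tibble::tibble(distance_to_focus = 1.5, delta_t = 4)
  b1 <- bin_by_distance(m)
  expect_identical(nrow(b1), 1L)
  expect_equal(b1$sd, 0)
  expect_identical(b1$n, 1L)
  # 1.0 and 1.9 share bin [0, 2); 2.0 starts bin [2, 4)
  m2 <- tibble::tibble(distance_to_focus = c(1.0, 1.9, 2.0), delta_t = c(2, 4, 6))
  b2 <- bin_by_distance(m2)
  expect_identical(nrow(b2), 2L)
  expect_equal(b2$delta_t, c(3, 6))
  expect_identical(b2$n, c(2L, 1L))
})
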