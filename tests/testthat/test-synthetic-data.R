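# Generators: linear fluorescence law, point-source heating field, seeded
# determinism, and the statistical structure of the downstream tables.

test_that("calibration series follows the linear fluorescence law exactly when noiseless", {
  sc <- noiseless_scene()
  series <- gen_calibration_series(sc, sensitivity = 0.017,
                                   temperatures = c(20, 30), ref_temp = 20)
  roi <- cell_roi_mask(sc)
  bg <- background_roi_mask(sc)
  totals <- vapply(series$images, quantify_cell_fluorescence, numeric(1),
                   cell_roi = roi, background_roi = bg)
  # reference-temperature identity and 1 - 0.017 * 10 = 0.83 scaling
  expect_equal(unname(totals[2] / totals[1]), 0.83, tolerance = 1e-9)
  # the ROI pad (3 px ~ 3 sigma of edge softening) clips a ~1e-4 occupancy tail
  expect_equal(unname(totals[1]), series$table$expected_total[1], tolerance = 1e-3)
})

test_that("zero sensitivity leaves the noiseless series constant and out-of-window temperatures reject", {
  sc <- noiseless_scene()
  # sensitivity of exactly 0 is outside (0, 0.1); the smallest usable value
  # must give identical images in the noiseless limit up to that epsilon
  series <- gen_calibration_series(sc, sensitivity = 1e-12,
                                   temperatures = c(16, 25, 39))
  expect_equal(series$images[[1]], series$images[[3]], tolerance = 1e-9)
  expect_error(gen_calibration_series(sc, 0.017, temperatures = c(10, 20)),
               "validity window")
  expect_error(gen_calibration_series(sc, 0.2, temperatures = c(20, 30)),
               "sensitivity")
})

test_that("generated images are non-negative and bit-reproducible under a fixed seed", {
  sc <- scene_spec(seed = 99, read_noise_sd = 3, shot_noise = TRUE)
  a <- gen_calibration_series(sc, 0.017, c(15, 25, 40))
  b <- gen_calibration_series(sc, 0.017, c(15, 25, 40))
  expect_identical(a$images, b$images)
  expect_true(all(vapply(a$images, function(m) all(m >= 0), logical(1))))
  pr1 <- gen_onoff_pair(sc, ref_profile(), focus = c(19.2, 19.2), power = 2)
  pr2 <- gen_onoff_pair(sc, ref_profile(), focus = c(19.2, 19.2), power = 2)
  expect_identical(pr1$on, pr2$on)
  expect_true(all(pr1$on >= 0) && all(pr1$off >= 0))
})

test_that("ON/OFF pair truth map encodes the exponential-decay field", {
  sc <- noiseless_scene()
  prof <- ref_profile()
  # focus on the centre of pixel (96, 96): x = (96 - 0.5) * 0.2 = 19.1 um;
  # pixel (96, 151) lies exactly 55 px = 11 um away along x
  pr <- gen_onoff_pair(sc, prof, focus = c(19.1, 19.1), power = 3.5)
  expect_equal(pr$truth_delta_t[96, 96], 14)  # slope x power at the focus
  expect_equal(pr$truth_delta_t[96, 151], 7)  # half at one half-distance
  expect_equal(max(pr$truth_delta_t), 14)
  # zero power: ON and OFF identical in expectation (noiseless => identical)
  pr0 <- gen_onoff_pair(sc, prof, focus = c(19.2, 19.2), power = 0)
  expect_equal(pr0$on, pr0$off)
  expect_error(gen_onoff_pair(sc, prof, focus = c(19.2, 19.2), power = -1),
               "non-negative")
  expect_error(gen_onoff_pair(sc, prof, focus = c(500, 500), power = 1),
               "outside")
})

test_that("cell measurement tables carry exact truth and seeded noise", {
  prof <- ref_profile()
  m0 <- gen_cell_measurements(prof, powers = 3, cell_distances = 0, noise_sd = 0)
  expect_equal(m0$delta_t, 12) # 3 mW x 4 degC/mW at the focus
  m1 <- gen_cell_measurements(prof, 2:3, c(0, 5, 12), noise_sd = 0.3, seed = 8)
  m2 <- gen_cell_measurements(prof, 2:3, c(0, 5, 12), noise_sd = 0.3, seed = 8)
  expect_identical(m1, m2)
  # decay monotonicity of the truth column
  d <- seq(0, 35, 2.5)
  mt <- gen_cell_measurements(prof, 3, d, noise_sd = 0)
  expect_true(all(diff(mt$delta_t_true) <= 0))
  # half-distance identity: dT(r_half) / dT(0) = 1/2 exactly
  mh <- gen_cell_measurements(prof, 3, c(0, 11), noise_sd = 0)
  expect_identical(mh$delta_t_true[2] / mh$delta_t_true[1], 0.5)
  expect_error(gen_cell_measurements(prof, 3, numeric(0)), "empty")
})

test_that("neurite tracks follow the growth schedule and reproduce under a seed", {
  tr <- gen_neurite_tracks(seq(0, 1, 0.1), growth_onset_stage = 0.3, rate = 20,
                           seed = 4)
  pre <- dplyr::filter(tr, stage == 0.2)
  expect_identical(nrow(pre), 1L) # single point before onset
  expect_equal(polyline_length(pre), 0)
  at8 <- dplyr::filter(tr, stage == 0.8)
  expect_equal(polyline_length(at8), 20 * (0.8 - 0.3), tolerance = 1e-9)
  expect_identical(tr, gen_neurite_tracks(seq(0, 1, 0.1), 0.3, 20, seed = 4))
})

test_that("division timings have the injected mean delay and degenerate limits", {
  exact <- gen_division_timings(10, mean_delay = 0, natural_sd = 0, seed = 1)
  expect_equal(exact$treated_time, exact$control_time)
  d <- gen_division_timings(50, mean_delay = 17, natural_sd = 5, seed = 2)
  expect_lt(abs(mean(d$treated_time - d$control_time) - 17), 2)
  # untreated left/right variability condition
  ctl <- gen_division_timings(200, mean_delay = 3, natural_sd = 4, seed = 3)
  expect_lt(abs(mean(ctl$treated_time - ctl$control_time) - 3), 1)
  expect_true(all(d$treated_time >= 0 & d$control_time >= 0))
})
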