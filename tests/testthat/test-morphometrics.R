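# Neurite lengths, staging, growth comparison, division timing and induction
# kinetics.

test_that("polyline_length matches hand geometry and the brute-force oracle", {
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(polyline_length(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               2 * sqrt(3))
  expect_equal(polyline_length(matrix(c(1, 2, 3), 1)), 0)
  expect_error(polyline_length(rbind(c(0, 0, 0), c(NA, 1, 1))), "non-finite")
  withr::with_seed(5, {
    for (i in 1:50) {
      pts <- matrix(rnorm(3 * sample(2:20, 1), sd = 10), ncol = 3)
      expect_equal(polyline_length(pts), brute_polyline_length(pts))
    }
  })
})

test_that("polyline_length is rigid-transform invariant and bounds the chord", {
  withr::with_seed(6, {
    for (i in 1:50) {
      pts <- matrix(rnorm(3 * sample(3:15, 1), sd = 5), ncol = 3)
      rot <- random_rotation()
      moved <- pts %*% t(rot) + matrix(rnorm(3), nrow(pts), 3, byrow = TRUE)
      expect_equal(polyline_length(moved), polyline_length(pts), tolerance = 1e-9)
      chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
      expect_gte(polyline_length(pts) + 1e-12, chord)
    }
  })
})

test_that("stage_ratio maps the anchors to 0 and 1 and clamps outside", {
  calib <- stage_calibration(comma_metric = 30, twofold_metric = 60)
  expect_equal(as.numeric(stage_ratio(30, calib)), 0)
  expect_equal(as.numeric(stage_ratio(60, calib)), 1)
  expect_equal(as.numeric(stage_ratio(45, calib)), 0.5)
  # strictly monotone between anchors
  vals <- as.numeric(stage_ratio(seq(30, 60, 2), calib))
  expect_true(all(diff(vals) > 0))
  expect_warning(out <- stage_ratio(c(20, 70), calib), "clamped")
  expect_equal(as.numeric(out), c(0, 1))
  expect_identical(attr(out, "clamped"), c(TRUE, TRUE))
  expect_error(stage_calibration(30, 30), "differ")
})

test_that("growth_curve tracks the generator schedule and omits unstaged timepoints", {
  tr <- gen_neurite_tracks(seq(0, 1, 0.1), growth_onset_stage = 0.3, rate = 20,
                           seed = 2)
  gc <- growth_curve(tr)
  expect_equal(gc$length[gc$stage <= 0.3], rep(0, sum(gc$stage <= 0.3)))
  grown <- dplyr::filter(gc, stage > 0.3)
  expect_equal(grown$length, 20 * (grown$stage - 0.3), tolerance = 1e-9)
  # omitted (unstaged) timepoints vanish from the curve, no interpolation
  tr$stage[tr$time == 6] <- NA
  gc2 <- growth_curve(tr)
  expect_false(6 %in% gc2$time)
  expect_identical(nrow(gc2), nrow(gc) - 1L)
  # single-timepoint track
  one <- dplyr::filter(tr, time == 1)
  expect_identical(nrow(growth_curve(one)), 1L)
  expect_error(growth_curve(dplyr::mutate(tr, stage = NA_real_)), "staged")
})

test_that("compare_outgrowth recovers an injected onset difference", {
  stages <- seq(0, 1, 0.05)
  mk <- function(onset, seeds) {
    lapply(seeds, function(s) {
      growth_curve(gen_neurite_tracks(stages, onset, rate = 20,
                                      jitter_sd = 0.3, seed = s))
    })
  }
  ga <- mk(0.30, 1:5)
  gb <- mk(0.40, 6:10)
  cmp <- compare_outgrowth(ga, gb, n_boot = 300, seed = 1)
  onset_row <- dplyr::filter(cmp$comparison, quantity == "onset")
  expect_lt(abs(onset_row$difference - 0.10), 0.06)
  expect_error(compare_outgrowth(ga[1], gb, n_boot = 10), ">= 2 curves")
  # identical groups: onset difference 0 with CI covering 0
  same <- compare_outgrowth(ga, ga, n_boot = 300, seed = 2)
  row0 <- dplyr::filter(same$comparison, quantity == "onset")
  expect_equal(row0$difference, 0)
  expect_lte(row0$ci_lo, 0)
  expect_gte(row0$ci_hi, 0)
})

test_that("bootstrap CI covers a zero onset difference at near-nominal rate", {
  stages <- seq(0, 1, 0.05)
  covered <- vapply(1:20, function(rep) {
    ga <- lapply(1:6, function(s) {
      growth_curve(gen_neurite_tracks(stages, 0.3, 20, jitter_sd = 0.5,
                                      seed = 100 * rep + s))
    })
    gb <- lapply(7:12, function(s) {
      growth_curve(gen_neurite_tracks(stages, 0.3, 20, jitter_sd = 0.5,
                                      seed = 100 * rep + s))
    })
    cmp <- compare_outgrowth(ga, gb, n_boot = 200, seed = rep)
    row <- dplyr::filter(cmp$comparison, quantity == "onset")
    row$ci_lo <= 0 && row$ci_hi >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("division_delay_stats recovers injected delays and cycle increases", {
  flat <- tibble::tibble(treated_time = c(100, 120), control_time = c(100, 120))
  expect_equal(division_delay_stats(flat, percent_cycle = FALSE)$mean_delay, 0)
  d <- gen_division_timings(50, mean_delay = 17, natural_sd = 5, seed = 9)
  st <- division_delay_stats(d)
  expect_lt(abs(st$mean_delay - 17), 2)
  expect_lt(abs(st$percent_cycle_increase - 100 * 17 / 63), 4)
  # control mode: mean absolute left/right difference
  ctl <- tibble::tibble(treated_time = c(97, 103), control_time = c(100, 100))
  expect_equal(division_delay_stats(ctl, paired = FALSE, percent_cycle = FALSE)$mean_delay, 3)
  expect_error(division_delay_stats(flat, percent_cycle = TRUE), "cycle columns")
  # bias shrinks with n (checked at n = 200)
  big <- gen_division_timings(200, 17, 5, seed = 10)
  expect_lt(abs(division_delay_stats(big)$mean_delay - 17), 1)
})

test_that("kinetics curves are power-normalised and averaged across embryos", {
  s1 <- tibble::tibble(embryo_id = 1, time_h = 0:5, fluorescence = (0:5) * 10)
  expect_equal(kinetics_curve(s1, laser_power = 1)$mean_intensity, (0:5) * 10)
  two <- dplyr::bind_rows(s1, dplyr::mutate(s1, embryo_id = 2,
                                            fluorescence = fluorescence * 3))
  expect_equal(kinetics_curve(two, 1)$mean_intensity, (0:5) * 20)
  # same intensities at 20 vs 100 uW differ 5-fold after normalisation
  k20 <- kinetics_curve(s1, 20)
  k100 <- kinetics_curve(s1, 100)
  expect_equal(k20$mean_intensity, 5 * k100$mean_intensity)
  # grids misaligned beyond tolerance error out
  off <- dplyr::mutate(s1, embryo_id = 2, time_h = time_h + 0.4)
  expect_error(kinetics_curve(dplyr::bind_rows(s1, off), 1), "tolerance")
})
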