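# Induction and ablation planning.

test_that("induction power range brackets the heat-shock band", {
  prof <- ref_profile()
  plan <- plan_induction(prof, c(32, 34), neighbor_distance = 11, ambient = 20)
  expect_equal(plan$power_range, c(3.0, 3.5))
  expect_equal(plan$power, 3.25)
  expect_equal(plan$predicted_focal, 33)
  # neighbour at one half-distance: half the focal elevation above ambient
  expect_equal(plan$predicted_at_neighbor, 20 + 13 / 2)
  expect_true(plan$feasible)
  # the band-lower-edge option reproduces a 3.0 mW plan
  low <- plan_induction(prof, c(32, 34), neighbor_distance = 11, edge = "low")
  expect_equal(low$power, 3.0)
  expect_equal(low$predicted_focal, 32)
  expect_equal(low$predicted_at_neighbor, 26) # half of 12 added to 20
})

test_that("induction is infeasible when ambient reaches the band or neighbours overheat", {
  prof <- ref_profile()
  hot <- plan_induction(prof, c(32, 34), neighbor_distance = 11, ambient = 33)
  expect_false(hot$feasible)
  expect_match(hot$diagnostic, "above the band")
  near <- plan_induction(prof, c(32, 34), neighbor_distance = 0.1, ambient = 20)
  expect_false(near$feasible)
  expect_match(near$diagnostic, "neighbour")
})

test_that("feasible plans satisfy band and neighbour constraints over a parameter sweep", {
  withr::with_seed(21, {
    for (i in 1:200) {
      prof <- thermal_profile(slope = runif(1, 1, 8),
                              half_distance = runif(1, 4, 25),
                              ambient = runif(1, 10, 33))
      lo <- runif(1, 30, 35)
      band <- c(lo, lo + runif(1, 0.5, 4))
      nd <- runif(1, 1, 40)
      plan <- plan_induction(prof, band, neighbor_distance = nd,
                             ambient = prof$ambient)
      if (isTRUE(plan$feasible)) {
        expect_gte(plan$predicted_focal, band[1])
        expect_lte(plan$predicted_focal, band[2])
        expect_lt(plan$predicted_at_neighbor, band[1])
      }
    }
  })
})

test_that("raising ambient never widens the feasible power range", {
  prof <- ref_profile()
  widths <- vapply(seq(20, 31.5, 0.5), function(amb) {
    plan <- plan_induction(prof, c(32, 34), neighbor_distance = 11, ambient = amb)
    diff(plan$power_range)
  }, numeric(1))
  expect_true(all(diff(widths) <= 1e-12))
})

test_that("classify_cells labels by predicted temperature, monotonically in distance", {
  prof <- ref_profile()
  plan <- plan_induction(prof, c(32, 34), neighbor_distance = 11)
  # under the 3.25 mW midpoint plan the focal temperature is 33 degC, so only
  # cells within ~1.3 um stay above the 32 degC threshold
  cells <- tibble::tibble(x = c(0, 1, 40, 0), y = c(0, 0, 0, 0))
  out <- classify_cells(cells, plan, prof, focus = c(0, 0))
  expect_identical(out$label, c("induced", "induced", "sub-threshold", "induced"))
  # elevation at 40 um is ~8% of focal: 20 + 0.08 x 13 stays well below 32
  expect_lt(out$predicted_temp[3], 22)
  # monotone: any cell closer than an induced cell is induced
  d <- sort(out$distance_to_focus)
  lab <- out$label[order(out$distance_to_focus)]
  expect_true(all(cumsum(lab == "sub-threshold")[lab == "induced"] == 0))
  expect_error(classify_cells(cells, plan_induction(prof, c(32, 34), 11, ambient = 33),
                              prof, c(0, 0)),
               "infeasible")
})

test_that("ablation planning reaches lethal focus with sub-threshold neighbours", {
  prof41 <- thermal_profile(4.1, 11, 20)
  plan <- plan_ablation(prof41, lethal_temp = 50, neighbor_distance = 11,
                        peak_power = 13)
  expect_equal(plan$predicted_focal, 73.3)
  expect_equal(plan$exposure$averaged_power_mw, 0.6474)
  # time-averaged focal elevation ~ 2.65 degC; at the neighbour even less
  expect_equal(plan$exposure$averaged_power_mw * 4.1, 2.654, tolerance = 1e-3)
  expect_lt(plan$predicted_at_neighbor, 32)
  expect_true(plan$feasible)
  # minimum peak power from the lethal threshold
  plan4 <- plan_ablation(ref_profile(), lethal_temp = 50, neighbor_distance = 11)
  expect_equal(plan4$min_peak_power, 7.5)
  expect_equal(plan4$power, 7.5)
  expect_error(plan_ablation(ref_profile(), lethal_temp = 33, neighbor_distance = 11),
               "lethal_temp")
  weak <- plan_ablation(ref_profile(), lethal_temp = 50, neighbor_distance = 11,
                        peak_power = 2)
  expect_false(weak$feasible)
})
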