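# Tuning and sweep tests run at the coarser 0.1-ms step: step-refinement
# is established separately and the tuner only compares systolic
# pressures between grid neighbours ~1 mmHg apart.

test_that("systolic pressure increases with stressed blood volume", {
  p <- baseline_params()
  sbp <- vapply(c(420, 450, 500), function(sbv) {
    max(run_to_steady_state(p, SBV = sbv, settings = fast_settings())$P_ao)
  }, 0)
  expect_true(all(diff(sbp) > 0))
})

test_that("tuning lands on the grid point nearest the target and is idempotent", {
  p <- baseline_params()
  tuned <- tune_sbv(p, tuning_spec(), start_SBV = 450,
                    settings = fast_settings())
  expect_equal(tuned$summary$SBP, 87.2, tolerance = 0.5 / 87.2)
  # neighbours on the 1-ml grid are strictly worse or equal
  err <- function(sbv) {
    b <- run_to_steady_state(p, SBV = sbv, settings = fast_settings())
    abs(max(b$P_ao) - 87.2)
  }
  expect_lte(err(tuned$SBV), err(tuned$SBV - 1))
  expect_lte(err(tuned$SBV), err(tuned$SBV + 1))
  # re-tuning from the tuned point returns the same SBV (fixed point)
  again <- tune_sbv(p, tuning_spec(), start_SBV = tuned$SBV,
                    settings = fast_settings())
  expect_equal(again$SBV, tuned$SBV)
  # and tuning from a distant anchor on the same 1-ml grid agrees
  far <- tune_sbv(p, tuning_spec(), start_SBV = tuned$SBV + 57,
                  settings = fast_settings())
  expect_equal(far$SBV, tuned$SBV)
})

test_that("scenario grids are the protocol step sequences", {
  expect_equal(scenario_grid("Ees")$values, c(13.1, 9.8, 6.5, 3.2))
  expect_equal(scenario_grid("B")$values, c(0.075, 0.090, 0.105, 0.120))
  expect_equal(scenario_grid("SVR")$values, seq(0.8, 5.0, by = 0.7))
  g <- scenario_grid("PVR")
  expect_equal(g$values, 0.0001 + 0.075 * 0:7)
  expect_equal(g$diameters, c(0, 2, 2.5))
  # index labels computed from the grid endpoints
  expect_equal(round(resistance_index(g$values[1] + 0.0655 + 0.0492,
                                      0.58), 2), 1.11)
  expect_equal(round(resistance_index(g$values[8] + 0.0655 + 0.0492,
                                      0.58), 2), 6.18)
  expect_equal(scenario_grid("diameter")$values, seq(0, 4.5, by = 0.5))
  expect_error(scenario_grid("PVR", values = c(1, 3, 2)), "monotone")
})

test_that("a paired sweep is tidy and its D = 0 column is pairing-invariant", {
  p <- baseline_params()
  g2 <- scenario_grid("PVR", values = c(0.0751, 0.3001),
                      diameters = c(0, 2.5))
  sw <- run_scenario(p, g2, settings = fast_settings())
  expect_s3_class(sw, "fontan_sweep")
  expect_equal(nrow(sw), 4)   # |values| x |diameters|
  expect_true(all(abs(sw$SBP - 87.2) < 0.5))
  # D = 0 rows do not depend on which other diameters were requested
  g0 <- scenario_grid("PVR", values = c(0.0751, 0.3001), diameters = 0)
  sw0 <- run_scenario(p, g0, settings = fast_settings())
  d0 <- sw[sw$diameter == 0, ]
  rownames(d0) <- NULL
  expect_equal(d0$SBV_tuned, sw0$SBV_tuned)
  expect_equal(d0$CVP, sw0$CVP, tolerance = 1e-10)

  cmp <- compare_fenestration(sw, at_value = 0.3001)
  expect_lt(cmp$dCVP, 0)   # fenestration decompresses the conduit
  expect_lt(cmp$dSBV, 0)
  expect_lt(cmp$dSpO2, 0)
  expect_gt(cmp$dCI, 0)
  # comparing a diameter against itself nulls every delta
  self <- compare_fenestration(sw, at_value = 0.3001, diameters = c(0, 0))
  expect_equal(unlist(self[-1]), c(dCVP = 0, dSBV = 0, dCI = 0,
                                   dSpO2 = 0, dDBP = 0))
  expect_error(compare_fenestration(sw, at_value = 0.15), "no unique row")
})

test_that("fenestration monotonicity: wider orifice, lower saturation", {
  p <- baseline_params()
  g <- scenario_grid("diameter", values = c(0, 1.5, 3))
  sw <- run_scenario(p, g, settings = fast_settings())
  expect_equal(sw$SpO2[1], 99)
  expect_true(all(diff(sw$SpO2) < 0))
  expect_true(all(diff(sw$CVP) < 0))
})
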