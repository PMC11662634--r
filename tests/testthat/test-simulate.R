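test_that("initialize_state distributes SBV exactly and at uniform pressure", {
  p <- baseline_params()
  st <- initialize_state(p, 450)
  expect_equal(sum(st), 450)
  # uniform pressure across capacitors; chambers at the same EDPVR value
  Pc <- st[["V_Cv_s"]] / 24.2
  expect_equal(st[["V_Ca_s"]] / 0.61, Pc, tolerance = 1e-6)
  expect_equal(st[["V_Ca_p"]] / 3.97, Pc, tolerance = 1e-6)
  expect_equal(1.15 * (exp(0.0753 * st[["V_SV"]]) - 1), Pc, tolerance = 1e-6)
  expect_error(initialize_state(p, 0), "SBV below model minimum")
  expect_error(initialize_state(p, -5), "SBV below model minimum")
})

test_that("baseline converges to a periodic cycle with volume conserved", {
  beat <- baseline_beat()
  expect_true(attr(beat, "converged"))
  expect_lt(attr(beat, "beats"), 200)
  expect_lt(attr(beat, "volume_drift"), 1e-6)
  # periodicity: first and last sample states agree within tolerance
  v0 <- as.numeric(beat[1, state_names6()])
  v1 <- as.numeric(beat[nrow(beat), state_names6()])
  expect_lt(max(abs(v1 - v0)), attr(beat, "settings")$tol * 1.5)
  # total volume constant along the sampled beat
  tot <- rowSums(beat[, state_names6()])
  expect_lt(diff(range(tot)) / mean(tot), 1e-6)
  # converges at the coarser 0.1-ms step too
  b2 <- run_to_steady_state(baseline_params(), SBV = 450,
                            settings = integrator_settings(dt = 0.1))
  expect_true(attr(b2, "converged"))
})

test_that("summary scalars are stable under step halving", {
  p <- baseline_params()
  b1 <- run_to_steady_state(p, SBV = 450,
                            settings = integrator_settings(dt = 0.1))
  b2 <- run_to_steady_state(p, SBV = 450,
                            settings = integrator_settings(dt = 0.05))
  s1 <- summarize_beat(b1); s2 <- summarize_beat(b2)
  expect_lt(abs(s1$SBP - s2$SBP), 0.05)
  expect_lt(abs(s1$CVP - s2$CVP), 0.05)
  for (col in c("SBP", "DBP", "CVP", "CI", "SpO2"))
    expect_lt(abs(s1[[col]] - s2[[col]]) / abs(s2[[col]]), 1e-3)
})

test_that("the periodic cycle is independent of the initializer", {
  p <- baseline_params()
  s_uniform <- initialize_state(p, 450)
  # a deliberately different split of the same total volume
  s_skewed <- s_uniform + c(10, 2, -6, -12, 4, 2)
  expect_equal(sum(s_skewed), 450)
  b1 <- run_to_steady_state(p, state = s_uniform)
  b2 <- run_to_steady_state(p, state = s_skewed)
  s1 <- summarize_beat(b1, p); s2 <- summarize_beat(b2, p)
  for (col in c("SBP", "DBP", "CVP", "CI", "Q_s", "Q_p", "Q_f", "SpO2"))
    expect_lt(abs(s1[[col]] - s2[[col]]) / abs(s2[[col]]), 1e-3,
              label = col)
})

test_that("identical inputs give identical outputs", {
  p <- baseline_params()
  b1 <- run_to_steady_state(p, SBV = 450, settings = fast_settings())
  b2 <- run_to_steady_state(p, SBV = 450, settings = fast_settings())
  expect_identical(b1$P_ao, b2$P_ao)
  expect_identical(b1$V_Cv_s, b2$V_Cv_s)
})

test_that("non-convergence and bad inputs raise informative errors", {
  p <- baseline_params()
  expect_error(
    run_to_steady_state(p, SBV = 450,
                        settings = integrator_settings(dt = 0.05,
                                                       max_beats = 2)),
    "no periodic steady state")
  expect_error(run_to_steady_state(p), "supply SBV")
  expect_error(run_to_steady_state(p, state = c(1, 2, 3)), "six")
  expect_error(integrator_settings(dt = 2), "dt")
})
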