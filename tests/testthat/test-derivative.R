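# The state derivative is checked against an independently hand-assembled
# flow balance: pressures and branch flows recomputed from first
# principles here, without calling the package's element functions.

hand_derivative <- function(s, t, p) {
  Tc <- 750; DT <- 15
  act <- function(tt, tes) {
    tt <- tt %% Tc
    if (tt > 0 && tt < 2 * tes) 0.5 * (1 - cos(pi * tt / tes)) else 0
  }
  P_SV <- {
    e <- act(t, 200)
    e * 13.1 * s[1] + (1 - e) * 1.15 * (exp(0.0753 * s[1]) - 1)
  }
  P_SA <- {
    e <- act(t + DT, 120)
    e * 1.64 * s[2] + (1 - e) * 0.197 * (exp(0.865 * s[2]) - 1)
  }
  P_as <- s[3] / 0.61; P_vs <- s[4] / 24.2
  P_ap <- s[5] / 3.97; P_vp <- s[6] / 2.52
  Q_AV <- if (P_SV > P_as) (P_SV - P_as) / (0.001 + 0.0984) else 0
  Q_as <- (P_as - P_vs) / 1.5
  Q_pa <- (P_vs - P_ap) / (0.0491 + 0.0655)
  Q_ap <- (P_ap - P_vp) / 0.075
  Q_pv <- (P_vp - P_SA) / 0.0492
  dPf <- P_vs - P_SA
  Q_f <- if (p$fenestration$D == 0) 0 else
    sign(dPf) * pi * p$fenestration$D^2 / 8 *
      (if (abs(dPf) < 1e-3) abs(dPf) / sqrt(1e-3) else sqrt(abs(dPf)))
  Q_AVV <- if (P_SA > P_SV) (P_SA - P_SV) / 0.001 else 0
  c(Q_AVV - Q_AV, Q_pv + Q_f - Q_AVV, Q_AV - Q_as,
    Q_as - Q_pa - Q_f, Q_pa - Q_ap, Q_ap - Q_pv)
}

test_that("state derivative matches the hand-assembled network balance", {
  p <- baseline_params(2.5)
  for (s in random_states(8, seed = 7)) {
    for (t in c(0, 90, 210, 430, 740)) {
      d <- state_derivative(s, t, p)
      expect_equal(as.numeric(d), hand_derivative(unname(s), t, p),
                   tolerance = 1e-10)
    }
  }
})

test_that("the circuit conserves volume: derivative components sum to zero", {
  p <- baseline_params(2.5)
  for (s in random_states(10, seed = 11)) {
    for (t in c(0, 123, 375, 600)) {
      d <- state_derivative(s, t, p)
      # zero up to roundoff on the largest branch flow
      expect_lt(abs(sum(d)) / max(abs(d), 1), 1e-12)
    }
  }
})

test_that("equal pressures with closed valves give a zero derivative", {
  p <- baseline_params(0)
  # one common pressure P*, valves see no gradient, no fenestration
  Pst <- 5
  s <- c(V_SV = log(Pst / 1.15 + 1) / 0.0753,
         V_SA = log(Pst / 0.197 + 1) / 0.865,
         V_Ca_s = 0.61 * Pst, V_Cv_s = 24.2 * Pst,
         V_Ca_p = 3.97 * Pst, V_Cv_p = 2.52 * Pst)
  # at a fully diastolic phase (e = 0 for both chambers) all nodes sit
  # at P*, every gradient vanishes and the diodes are closed
  d <- state_derivative(s, 500, p)
  expect_equal(as.numeric(d), rep(0, 6), tolerance = 1e-9)
})

test_that("a closed fenestration is identical to removing the branch", {
  p0 <- baseline_params(0)
  # oracle with the branch structurally absent
  no_branch <- function(s, t) {
    d <- hand_derivative(unname(s), t, p0)
    d  # hand_derivative already sets Q_f = 0 when D == 0
  }
  for (s in random_states(5, seed = 3)) {
    for (t in c(10, 300, 700)) {
      d <- state_derivative(s, t, p0)
      expect_identical(attr(d, "flows")[["Q_f"]], 0)
      expect_equal(as.numeric(d), no_branch(s, t), tolerance = 1e-10)
    }
  }
  # trajectory equivalence: D = 0 run equals a run whose fenestration
  # branch contributes exactly nothing, bitwise on the sampled beat
  b0 <- run_to_steady_state(p0, SBV = 450, settings = fast_settings())
  expect_true(all(b0$Q_f == 0))
})

test_that("compiled right-hand side agrees with the R reference", {
  p <- baseline_params(2.5)
  for (s in random_states(6, seed = 19)) {
    for (t in c(0, 55, 333, 749)) {
      dr <- state_derivative(s, t, p)
      dc <- fontansim:::.rhs_compiled(s, t, p)
      expect_equal(as.numeric(dr), as.numeric(dc), tolerance = 1e-12)
      expect_equal(as.numeric(attr(dr, "flows")),
                   as.numeric(attr(dc, "flows")), tolerance = 1e-12)
    }
  }
})
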