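# Element equations of the circuit, as plain R functions. These are the
# reference definitions; the compiled integrator repeats them for speed
# and is tested against this surface.

#' Normalized elastance (activation) curve
#'
#' Half-cosine activation: `e(t) = 0.5 * (1 - cos(pi * t / T_es))` for
#' `0 < t < 2*T_es` and 0 for the rest of the cycle. `e` peaks at 1 when
#' `t = T_es` and is continuous at `t = 2*T_es`. `t` must already be
#' reduced modulo the cycle length; any consistent time unit works since
#' only the ratio `t/T_es` enters.
#'
#' @param t time since the start of the chamber's systole (same unit as
#'   `T_es`), in `[0, T_c)`.
#' @param T_es time to end systole.
#' @return Dimensionless activation in `[0, 1]`; vectorized over `t`.
#' @examples
#' normalized_elastance(c(0, 100, 200, 450), T_es = 200)
#' @export
normalized_elastance <- function(t, T_es) {
  stopifnot(T_es > 0, all(t >= 0))
  ifelse(t > 0 & t < 2 * T_es, 0.5 * (1 - cos(pi * t / T_es)), 0)
}

#' Instantaneous chamber pressure
#'
#' Time-varying elastance interpolation between the end-systolic and
#' end-diastolic pressure-volume relations:
#' `P = e*E_es*(V - V_0) + (1 - e)*A*(exp(B*(V - V_0)) - 1)`.
#' Negative pressures for `V < V_0` are allowed (the EDPVR is negative
#' there); with the default `V_0 = 0` they cannot arise from nonnegative
#' volumes.
#'
#' @param V chamber volume, ml.
#' @param phase_t time since the chamber's systole start, ms, in
#'   `[0, T_c)`.
#' @param p a [chamber_params()] object.
#' @return Pressure in mmHg; vectorized over `V`/`phase_t`.
#' @export
chamber_pressure <- function(V, phase_t, p) {
  stopifnot(inherits(p, "chamber_params"))
  e <- normalized_elastance(phase_t, p$T_es)
  e * p$E_es * (V - p$V_0) + (1 - e) * p$A * (exp(p$B * (V - p$V_0)) - 1)
}

#' Linear capacitor pressure
#'
#' @param V stored volume, ml.
#' @param C capacitance, ml/mmHg (> 0).
#' @return Pressure `V / C` in mmHg.
#' @export
capacitor_pressure <- function(V, C) {
  stopifnot(C > 0)
  V / C
}

#' Flow through an ideal diode valve with series resistance
#'
#' Forward flow `(P_up - P_down) / R` when the gradient is positive,
#' zero otherwise (no regurgitation).
#'
#' @param P_up,P_down upstream and downstream pressures, mmHg.
#' @param R forward resistance, mmHg·s/ml (> 0).
#' @return Flow in ml/s, never negative.
#' @export
valve_flow <- function(P_up, P_down, R) {
  stopifnot(R > 0)
  pmax(0, P_up - P_down) / R
}

#' Fenestration flow from the orifice pressure gradient
#'
#' Inverts the simplified Bernoulli relation
#' `dP = 64 * Q_f^2 / (pi^2 * D^4)` (with `dP` in mmHg, velocity in m/s)
#' to `Q_f = sign(dP) * (pi * D^2 / 8) * sqrt(|dP|)` in ml/s for `D` in
#' mm. The orifice is bidirectional; positive `dP` (venous above atrial
#' pressure) gives right-to-left flow into the atrium. For
#' `|dP| < eps` the square root is replaced by the linear blend
#' `|dP| / sqrt(eps)` so the flow derivative stays bounded at `dP = 0`.
#'
#' @param dP pressure gradient conduit minus atrium, mmHg.
#' @param D effective diameter, mm; `D = 0` gives exactly zero flow.
#' @param eps regularization threshold, mmHg.
#' @return Flow in ml/s, sign-matched to `dP`; vectorized over `dP`.
#' @examples
#' fenestration_flow(4, 2.5)   # ~4.909 ml/s
#' @export
fenestration_flow <- function(dP, D, eps = 1e-3) {
  stopifnot(D >= 0, eps > 0)
  if (D == 0) return(rep(0, length(dP)))
  ad <- abs(dP)
  root <- ifelse(ad < eps, ad / sqrt(eps), sqrt(ad))
  sign(dP) * pi * D^2 / 8 * root
}

#' State derivative of the closed Fontan circuit
#'
#' Assembles the six compartment volume derivatives from the element
#' equations. The circuit is the series loop
#' ventricle -> (aortic diode + R_AV + R_c,s) -> C_a,s -> R_a,s ->
#' C_v,s -> (R_v,s + R_c,p) -> C_a,p -> R_a,p -> C_v,p -> R_v,p ->
#' atrium -> (AV-valve diode + R_AVV) -> ventricle, with the
#' fenestration shunting C_v,s (the cavopulmonary conduit) directly to
#' the atrium. Atrial activation is evaluated at phase
#' `(t + DT) mod T_c`, ventricular at `t mod T_c`, so the atrium leads
#' by `DT`. The six derivatives sum to zero identically: the circuit is
#' closed and the fenestration only moves volume internally.
#'
#' @param state named numeric vector of the six compartment volumes, ml,
#'   in the order `V_SV, V_SA, V_Ca_s, V_Cv_s, V_Ca_p, V_Cv_p`.
#' @param t time, ms (any nonnegative value; reduced modulo `T_c`
#'   internally).
#' @param params a [fontan_params()] bundle.
#' @param eps fenestration regularization threshold, mmHg.
#' @return Named numeric vector of dV/dt in ml/s, with attributes
#'   `flows` (`Q_AV, Q_as, Q_pa, Q_ap, Q_pv, Q_f, Q_AVV`, ml/s) and
#'   `pressures` (`P_SV, P_SA, P_Ca_s, P_Cv_s, P_Ca_p, P_Cv_p`, mmHg).
#' @export
state_derivative <- function(state, t, params, eps = 1e-3) {
  stopifnot(length(state) == 6, t >= 0)
  validate_fontan_params(params)
  Tc <- params$timing$T_c
  DT <- params$timing$DT_fraction * Tc
  s <- unname(state)

  P_SV <- chamber_pressure(s[1], t %% Tc, params$SV)
  P_SA <- chamber_pressure(s[2], (t + DT) %% Tc, params$SA)
  P_Ca_s <- capacitor_pressure(s[3], params$systemic$C_a)
  P_Cv_s <- capacitor_pressure(s[4], params$systemic$C_v)
  P_Ca_p <- capacitor_pressure(s[5], params$pulmonary$C_a)
  P_Cv_p <- capacitor_pressure(s[6], params$pulmonary$C_v)

  Q_AV <- valve_flow(P_SV, P_Ca_s, params$AV$R_fwd + params$systemic$R_c)
  Q_as <- (P_Ca_s - P_Cv_s) / params$systemic$R_a
  Q_pa <- (P_Cv_s - P_Ca_p) / (params$systemic$R_v + params$pulmonary$R_c)
  Q_ap <- (P_Ca_p - P_Cv_p) / params$pulmonary$R_a
  Q_pv <- (P_Cv_p - P_SA) / params$pulmonary$R_v
  Q_f <- fenestration_flow(P_Cv_s - P_SA, params$fenestration$D, eps)
  Q_AVV <- valve_flow(P_SA, P_SV, params$AVV$R_fwd)

  d <- c(V_SV = Q_AVV - Q_AV,
         V_SA = Q_pv + Q_f - Q_AVV,
         V_Ca_s = Q_AV - Q_as,
         V_Cv_s = Q_as - Q_pa - Q_f,
         V_Ca_p = Q_pa - Q_ap,
         V_Cv_p = Q_ap - Q_pv)
  attr(d, "flows") <- c(Q_AV = Q_AV, Q_as = Q_as, Q_pa = Q_pa, Q_ap = Q_ap,
                        Q_pv = Q_pv, Q_f = Q_f, Q_AVV = Q_AVV)
  attr(d, "pressures") <- c(P_SV = P_SV, P_SA = P_SA, P_Ca_s = P_Ca_s,
                            P_Cv_s = P_Cv_s, P_Ca_p = P_Ca_p, P_Cv_p = P_Cv_p)
  d
}
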