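#' Integrator settings
#'
#' Fixed-step fourth-order Runge-Kutta settings. The default step of
#' 0.05 ms keeps the fast atrioventricular-valve mode (series
#' resistance 0.001 mmHg·s/ml against the stiff atrial EDPVR) well
#' inside the RK4 stability region across the sweep protocols while a
#' single configuration still converges in well under a second.
#'
#' @param dt step size, ms (must be in (0, 1]).
#' @param max_beats maximum number of beats before declaring
#'   non-convergence.
#' @param tol periodicity tolerance: maximum absolute change of any
#'   state component between consecutive end-of-beat states, ml.
#' @return A list of class `integrator_settings`.
#' @export
integrator_settings <- function(dt = 0.05, max_beats = 200, tol = 1e-3) {
  if (!is.finite(dt) || dt <= 0 || dt > 1)
    stop("dt must be in (0, 1] ms", call. = FALSE)
  if (max_beats < 2) stop("max_beats must be >= 2", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(list(dt = dt, max_beats = max_beats, tol = tol),
            class = "integrator_settings")
}

#' Distribute stressed blood volume across the compartments
#'
#' Builds an initial state by placing the whole stressed blood volume
#' `SBV` at a single uniform pressure `P*`: capacitors take `C_i * P*`,
#' chambers take their end-diastolic (e = 0) pressure-volume relation
#' inverted at `P*`, i.e. `V = V_0 + log(P*/A + 1)/B`. `P*` is solved so
#' the volumes sum to `SBV`; any sub-tolerance residual is folded into
#' the systemic venous compartment so the components sum to `SBV`
#' exactly.
#'
#' @param params a [fontan_params()] bundle.
#' @param SBV total stressed blood volume, ml (> 0).
#' @return Named state vector of the six compartment volumes, ml.
#' @export
initialize_state <- function(params, SBV) {
  validate_fontan_params(params)
  if (!is.finite(SBV) || SBV <= 0)
    stop("SBV below model minimum", call. = FALSE)
  chamber_v <- function(P, ch) ch$V_0 + log(P / ch$A + 1) / ch$B
  total <- function(P) {
    P * (params$systemic$C_a + params$systemic$C_v +
         params$pulmonary$C_a + params$pulmonary$C_v) +
      chamber_v(P, params$SV) + chamber_v(P, params$SA)
  }
  hi <- 1
  while (total(hi) < SBV) {
    hi <- hi * 2
    if (hi > 1e6) stop("SBV initialization failed to bracket", call. = FALSE)
  }
  Pstar <- uniroot(function(P) total(P) - SBV, c(0, hi), tol = 1e-12)$root
  st <- c(V_SV = chamber_v(Pstar, params$SV),
          V_SA = chamber_v(Pstar, params$SA),
          V_Ca_s = Pstar * params$systemic$C_a,
          V_Cv_s = Pstar * params$systemic$C_v,
          V_Ca_p = Pstar * params$pulmonary$C_a,
          V_Cv_p = Pstar * params$pulmonary$C_v)
  st["V_Cv_s"] <- st["V_Cv_s"] + (SBV - sum(st))
  st
}

#' Run the circuit to a periodic steady state
#'
#' Integrates the six-compartment ODE system beat by beat with
#' fixed-step RK4 until the end-of-beat state repeats to within
#' `settings$tol` in every component, then returns one further full
#' beat sampled at every integration step.
#'
#' @param params a [fontan_params()] bundle.
#' @param SBV stressed blood volume, ml; used to build the initial state
#'   via [initialize_state()]. Ignored when `state` is given.
#' @param settings an [integrator_settings()] object.
#' @param state optional explicit initial state (named or unnamed vector
#'   of the six compartment volumes); overrides `SBV`.
#' @return An object of class `fontan_beat`: a data frame with one row
#'   per sample over one cycle, columns `t` (ms within the cycle),
#'   pressures `P_SV, P_SA, P_Ca_s, P_Cv_s, P_Ca_p, P_Cv_p` (mmHg),
#'   flows `Q_AV, Q_as, Q_pa, Q_ap, Q_pv, Q_f, Q_AVV` (ml/s) and the six
#'   state volumes (ml). Attributes: `params`, `settings`, `SBV` (total
#'   volume, ml), `converged`, `beats`, `delta` (final beat-to-beat
#'   change, ml), `dt` (actual step, ms).
#' @examples
#' \donttest{
#' beat <- run_to_steady_state(fontan_params(), SBV = 450)
#' attr(beat, "beats")
#' }
#' @export
run_to_steady_state <- function(params, SBV = NULL,
                                settings = integrator_settings(),
                                state = NULL) {
  validate_fontan_params(params)
  stopifnot(inherits(settings, "integrator_settings"))
  if (is.null(state)) {
    if (is.null(SBV)) stop("supply SBV or an explicit state", call. = FALSE)
    state <- initialize_state(params, SBV)
  } else {
    if (length(state) != 6 || any(!is.finite(state)) || any(state < 0))
      stop("state must be six finite nonnegative volumes", call. = FALSE)
    state <- as.numeric(state)
  }
  total0 <- sum(state)

  res <- .fontan_simulate_cpp(as.numeric(state), .flatten_params(params),
                              settings$dt / 1000, as.integer(settings$max_beats),
                              settings$tol)
  if (res$bad_component > 0)
    stop(sprintf(
      "integration failure: component %s became non-finite or negative near t = %.0f ms (beat %d); try a smaller dt",
      state_names()[res$bad_component], res$bad_time * 1000, res$beats),
      call. = FALSE)
  if (!res$converged)
    stop(sprintf(
      "no periodic steady state within %d beats (last beat-to-beat change %.3g ml, tolerance %.3g ml)",
      settings$max_beats, res$delta, settings$tol), call. = FALSE)

  drift <- abs(res$v_total_end - total0) / total0
  if (drift > 1e-6)
    warning(sprintf("total volume drifted by %.3g relative over the run", drift))

  out <- data.frame(t = res$times * 1000)
  P <- res$P; colnames(P) <- c("P_SV", "P_SA", "P_Ca_s", "P_Cv_s",
                               "P_Ca_p", "P_Cv_p")
  Q <- res$Q; colnames(Q) <- c("Q_AV", "Q_as", "Q_pa", "Q_ap", "Q_pv",
                               "Q_f", "Q_AVV")
  V <- res$V; colnames(V) <- state_names()
  out <- cbind(out, as.data.frame(P), as.data.frame(Q), as.data.frame(V))
  # aortic (root) pressure: the Windkessel input node proximal to the
  # characteristic impedance. With the valve open it is ventricular
  # pressure less the small valve drop; with the valve closed the root
  # rests at the arterial-capacitor pressure.
  out$P_ao <- ifelse(out$Q_AV > 0,
                     out$P_SV - out$Q_AV * params$AV$R_fwd,
                     out$P_Ca_s)
  structure(out,
            class = c("fontan_beat", "data.frame"),
            params = params, settings = settings,
            SBV = total0, converged = res$converged,
            beats = res$beats, delta = res$delta, dt = res$dt * 1000,
            volume_drift = drift)
}

#' @export
print.fontan_beat <- function(x, ...) {
  cat(sprintf(
    "One converged cardiac cycle: %d samples over %.1f ms (dt %.3g ms)\n",
    nrow(x), max(x$t), attr(x, "dt")))
  cat(sprintf("  converged after %d beats (delta %.2g ml), total volume %.1f ml\n",
              attr(x, "beats"), attr(x, "delta"), attr(x, "SBV")))
  invisible(x)
}

# Direct access to the compiled right-hand side, for cross-checking the
# compiled engine against state_derivative(). t in ms.
.rhs_compiled <- function(state, t, params, eps = 1e-3) {
  .fontan_rhs_cpp(as.numeric(state), t / 1000, .flatten_params(params, eps))
}
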