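#' Cardiac chamber parameters
#'
#' A chamber follows the time-varying elastance model: instantaneous
#' pressure interpolates between a linear end-systolic pressure-volume
#' relation (slope `E_es`, volume intercept `V_0`) and an exponential
#' end-diastolic relation `A * (exp(B * (V - V_0)) - 1)` via the
#' activation function [normalized_elastance()].
#'
#' @param E_es end-systolic elastance, mmHg/ml.
#' @param A scaling factor of the EDPVR, mmHg.
#' @param B exponent (stiffness constant) of the EDPVR, 1/ml.
#' @param V_0 unstressed volume at which end-systolic pressure is zero, ml.
#' @param T_es time to end systole, ms.
#' @return A list of class `chamber_params`.
#' @export
chamber_params <- function(E_es, A, B, V_0 = 0, T_es = 200) {
  stopifnot(is.numeric(E_es), is.numeric(A), is.numeric(B),
            is.numeric(V_0), is.numeric(T_es))
  if (E_es <= 0) stop("E_es must be > 0", call. = FALSE)
  if (A < 0) stop("A must be >= 0", call. = FALSE)
  if (B <= 0) stop("B must be > 0", call. = FALSE)
  if (V_0 < 0) stop("V_0 must be >= 0", call. = FALSE)
  if (T_es <= 0) stop("T_es must be > 0", call. = FALSE)
  structure(list(E_es = E_es, A = A, B = B, V_0 = V_0, T_es = T_es),
            class = "chamber_params")
}

#' Modified Windkessel bed parameters
#'
#' One vascular bed: characteristic impedance `R_c` proximal to the
#' arterial capacitor `C_a`, arterial resistance `R_a` between arterial
#' and venous capacitors, venous capacitor `C_v`, and venous resistance
#' `R_v` draining the bed.
#'
#' @param R_c characteristic impedance, mmHg·s/ml.
#' @param R_a arterial (resistive) element, mmHg·s/ml.
#' @param R_v venous resistance, mmHg·s/ml.
#' @param C_a arterial capacitance, ml/mmHg.
#' @param C_v venous capacitance, ml/mmHg.
#' @return A list of class `windkessel_params`.
#' @export
windkessel_params <- function(R_c, R_a, R_v, C_a, C_v) {
  vals <- c(R_c = R_c, R_a = R_a, R_v = R_v, C_a = C_a, C_v = C_v)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Windkessel resistances and capacitances must be > 0",
         call. = FALSE)
  structure(as.list(vals), class = "windkessel_params")
}

#' Valve parameters (ideal diode with a series resistor)
#'
#' @param R_fwd forward resistance, mmHg·s/ml.
#' @return A list of class `valve_params`.
#' @export
valve_params <- function(R_fwd = 0.001) {
  if (!is.finite(R_fwd) || R_fwd <= 0)
    stop("R_fwd must be > 0", call. = FALSE)
  structure(list(R_fwd = R_fwd), class = "valve_params")
}

#' Fenestration parameters
#'
#' `D` is the effective orifice diameter in mm; `D = 0` closes the
#' fenestration (the shunt branch carries exactly zero flow).
#'
#' @param D effective diameter, mm.
#' @return A list of class `fenestration_params`.
#' @export
fenestration_params <- function(D = 2.5) {
  if (!is.finite(D) || D < 0) stop("D must be >= 0", call. = FALSE)
  structure(list(D = D), class = "fenestration_params")
}

#' Cardiac timing parameters
#'
#' The cycle length is `T_c = 60000/HR` ms. Atrial activation leads
#' ventricular activation by `DT_fraction * T_c` (15 ms at 80 bpm).
#'
#' @param HR heart rate, beats/min.
#' @param DT_fraction atrial systole time advance as a fraction of the
#'   cycle length.
#' @return A list of class `timing_params` with fields `HR`, `T_c` (ms)
#'   and `DT_fraction`.
#' @export
timing_params <- function(HR = 80, DT_fraction = 0.02) {
  if (!is.finite(HR) || HR <= 0) stop("HR must be > 0", call. = FALSE)
  if (!is.finite(DT_fraction) || DT_fraction < 0 || DT_fraction >= 1)
    stop("DT_fraction must be in [0, 1)", call. = FALSE)
  structure(list(HR = HR, T_c = 60000 / HR, DT_fraction = DT_fraction),
            class = "timing_params")
}

#' Oxygen balance constants
#'
#' Constants of the Fick shunt balance: pulmonary venous saturation,
#' whole-body oxygen consumption indexed to body surface area,
#' hemoglobin, and the fixed conversion factors (1.34 ml O2 per g Hb,
#' 10 dl per L).
#'
#' @param S_pv_O2 pulmonary venous O2 saturation, fraction in (0, 1].
#' @param CVO2 whole-body O2 consumption, ml O2/min/m^2.
#' @param Hb hemoglobin concentration, g/dl.
#' @param BSA body surface area, m^2.
#' @return A list of class `oxygen_params`.
#' @export
oxygen_params <- function(S_pv_O2 = 0.99, CVO2 = 185, Hb = 14, BSA = 0.58) {
  if (!is.finite(S_pv_O2) || S_pv_O2 <= 0 || S_pv_O2 > 1)
    stop("S_pv_O2 must be in (0, 1]", call. = FALSE)
  if (any(c(CVO2, Hb, BSA) <= 0))
    stop("CVO2, Hb and BSA must be > 0", call. = FALSE)
  structure(list(S_pv_O2 = S_pv_O2, CVO2 = CVO2, Hb = Hb, BSA = BSA,
                 hb_o2_capacity = 1.34, dl_per_l = 10),
            class = "oxygen_params")
}

#' Full Fontan model parameter bundle
#'
#' Defaults are the baseline parameter set of the calibrated model: a
#' single ventricle and single atrium, aortic and atrioventricular
#' diode valves, systemic and pulmonary modified Windkessel beds, a
#' 2.5-mm fenestration between the systemic venous compartment (the
#' cavopulmonary conduit) and the atrium, 80 bpm, and BSA 0.58 m^2.
#'
#' @param SV,SA ventricular and atrial [chamber_params()].
#' @param AV,AVV aortic and atrioventricular [valve_params()].
#' @param systemic,pulmonary [windkessel_params()] for the two beds.
#' @param fenestration [fenestration_params()].
#' @param timing [timing_params()].
#' @param BSA body surface area, m^2.
#' @param oxygen [oxygen_params()] used by the saturation solver.
#' @return A list of class `fontan_params`.
#' @examples
#' p <- fontan_params()                        # baseline, D = 2.5 mm
#' p0 <- fontan_params(fenestration = fenestration_params(0))
#' @export
fontan_params <- function(SV = chamber_params(E_es = 13.1, A = 1.15,
                                              B = 0.0753, V_0 = 0, T_es = 200),
                          SA = chamber_params(E_es = 1.64, A = 0.197,
                                              B = 0.865, V_0 = 0, T_es = 120),
                          AV = valve_params(0.001),
                          AVV = valve_params(0.001),
                          systemic = windkessel_params(R_c = 0.0984, R_a = 1.5,
                                                       R_v = 0.0491,
                                                       C_a = 0.61, C_v = 24.2),
                          pulmonary = windkessel_params(R_c = 0.0655,
                                                        R_a = 0.075,
                                                        R_v = 0.0492,
                                                        C_a = 3.97, C_v = 2.52),
                          fenestration = fenestration_params(2.5),
                          timing = timing_params(HR = 80),
                          BSA = 0.58,
                          oxygen = oxygen_params()) {
  p <- structure(list(SV = SV, SA = SA, AV = AV, AVV = AVV,
                      systemic = systemic, pulmonary = pulmonary,
                      fenestration = fenestration, timing = timing,
                      BSA = BSA, oxygen = oxygen),
                 class = "fontan_params")
  validate_fontan_params(p)
  p
}

#' Validate a Fontan parameter bundle
#'
#' Checks all component invariants plus the cross-field constraints:
#' each chamber must satisfy `2 * T_es <= T_c`, and `BSA > 0`.
#'
#' @param p a `fontan_params` object.
#' @return `p`, invisibly; errors name the offending field.
#' @export
validate_fontan_params <- function(p) {
  stopifnot(inherits(p, "fontan_params"))
  for (nm in c("SV", "SA")) {
    ch <- p[[nm]]
    if (!inherits(ch, "chamber_params"))
      stop(nm, " must be chamber_params", call. = FALSE)
    if (2 * ch$T_es > p$timing$T_c)
      stop(nm, ": 2*T_es (", 2 * ch$T_es, " ms) exceeds cycle length T_c (",
           p$timing$T_c, " ms)", call. = FALSE)
  }
  for (nm in c("AV", "AVV"))
    if (!inherits(p[[nm]], "valve_params"))
      stop(nm, " must be valve_params", call. = FALSE)
  for (nm in c("systemic", "pulmonary"))
    if (!inherits(p[[nm]], "windkessel_params"))
      stop(nm, " must be windkessel_params", call. = FALSE)
  if (!inherits(p$fenestration, "fenestration_params"))
    stop("fenestration must be fenestration_params", call. = FALSE)
  if (!inherits(p$timing, "timing_params"))
    stop("timing must be timing_params", call. = FALSE)
  if (!is.finite(p$BSA) || p$BSA <= 0)
    stop("BSA must be > 0", call. = FALSE)
  if (!inherits(p$oxygen, "oxygen_params"))
    stop("oxygen must be oxygen_params", call. = FALSE)
  invisible(p)
}

#' @export
print.fontan_params <- function(x, ...) {
  cat("Fontan circulation parameters\n")
  cat(sprintf("  HR %g bpm (T_c %g ms), BSA %g m^2, fenestration D %g mm\n",
              x$timing$HR, x$timing$T_c, x$BSA, x$fenestration$D))
  cat(sprintf("  SV: E_es %g, A %g, B %g, V_0 %g, T_es %g ms\n",
              x$SV$E_es, x$SV$A, x$SV$B, x$SV$V_0, x$SV$T_es))
  cat(sprintf("  SA: E_es %g, A %g, B %g, V_0 %g, T_es %g ms\n",
              x$SA$E_es, x$SA$A, x$SA$B, x$SA$V_0, x$SA$T_es))
  cat(sprintf("  systemic:  R_c %g, R_a %g, R_v %g, C_a %g, C_v %g\n",
              x$systemic$R_c, x$systemic$R_a, x$systemic$R_v,
              x$systemic$C_a, x$systemic$C_v))
  cat(sprintf("  pulmonary: R_c %g, R_a %g, R_v %g, C_a %g, C_v %g\n",
              x$pulmonary$R_c, x$pulmonary$R_a, x$pulmonary$R_v,
              x$pulmonary$C_a, x$pulmonary$C_v))
  invisible(x)
}

# State component names, fixed order shared with the compiled engine.
state_names <- function() {
  c("V_SV", "V_SA", "V_Ca_s", "V_Cv_s", "V_Ca_p", "V_Cv_p")
}

# Flatten a fontan_params bundle into the numeric vector the compiled
# engine consumes. Times converted ms -> s here; everything else is
# already in mmHg/ml/s units.
.flatten_params <- function(p, eps = 1e-3) {
  validate_fontan_params(p)
  c(p$SV$E_es, p$SV$A, p$SV$B, p$SV$V_0, p$SV$T_es / 1000,
    p$SA$E_es, p$SA$A, p$SA$B, p$SA$V_0, p$SA$T_es / 1000,
    p$AV$R_fwd, p$AVV$R_fwd,
    p$systemic$R_c, p$systemic$R_a, p$systemic$R_v,
    p$systemic$C_a, p$systemic$C_v,
    p$pulmonary$R_c, p$pulmonary$R_a, p$pulmonary$R_v,
    p$pulmonary$C_a, p$pulmonary$C_v,
    p$fenestration$D, p$timing$T_c / 1000,
    p$timing$DT_fraction * p$timing$T_c / 1000, eps)
}
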