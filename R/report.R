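#' Arterial and venous oxygen saturations from the shunt balance
#'
#' Solves the two-equation Fick system coupling flows and saturations:
#' atrial (arterial) oxygen content is the flow-weighted mix of
#' pulmonary venous blood (saturation `S_pv_O2`) and fenestration blood
#' (systemic venous saturation), and the arteriovenous content
#' difference carries the whole-body oxygen consumption:
#' \deqn{SaO_2 (1.34 \cdot Hb \cdot 10 \cdot Q_s) =
#'       S_{pv}O_2 (1.34 \cdot Hb \cdot 10 \cdot Q_p) +
#'       SvO_2 (1.34 \cdot Hb \cdot 10 \cdot Q_f)}
#' \deqn{CVO_2 \cdot BSA = (1.34 \cdot Hb \cdot 10 \cdot Q_s)(SaO_2 - SvO_2)}
#' The closed form is `SaO2 = S_pv_O2 - k * Q_f/Q_p` and
#' `SvO2 = SaO2 - k` with `k = CVO2*BSA / (1.34*Hb*10*Q_s)`.
#' Saturations are never clamped: an infeasible configuration (venous
#' saturation at or below zero) raises an error, signalling that the
#' operating point is outside model validity.
#'
#' @param Q_s systemic (aortic) flow, L/min (> 0).
#' @param Q_p pulmonary flow, L/min (> 0).
#' @param Q_f fenestration flow, L/min (>= 0); `Q_s` must equal
#'   `Q_p + Q_f` within 0.5\% (steady-state continuity).
#' @param ox an [oxygen_params()] object.
#' @return List with `SaO2` and `SvO2` as fractions.
#' @examples
#' oxygen_saturations(1.5, 1.2, 0.3)   # SaO2 0.8947, SvO2 0.5134
#' @export
oxygen_saturations <- function(Q_s, Q_p, Q_f, ox = oxygen_params()) {
  stopifnot(inherits(ox, "oxygen_params"))
  if (Q_s <= 0 || Q_p <= 0 || Q_f < 0)
    stop("flows must satisfy Q_s > 0, Q_p > 0, Q_f >= 0", call. = FALSE)
  if (abs(Q_s - (Q_p + Q_f)) > 0.005 * Q_s)
    stop(sprintf("flow continuity violated: Q_s = %.4f but Q_p + Q_f = %.4f",
                 Q_s, Q_p + Q_f), call. = FALSE)
  k <- ox$CVO2 * ox$BSA / (ox$hb_o2_capacity * ox$Hb * ox$dl_per_l * Q_s)
  # exact solution of the two balance equations as written; reduces to
  # SaO2 = S_pv_O2 - k * Q_f/Q_p when Q_s = Q_p + Q_f holds exactly
  SaO2 <- (ox$S_pv_O2 * Q_p - k * Q_f) / (Q_s - Q_f)
  SvO2 <- SaO2 - k
  if (SvO2 <= 0 || SaO2 <= 0)
    stop("oxygen transport infeasible at this flow", call. = FALSE)
  list(SaO2 = SaO2, SvO2 = SvO2)
}

#' Vascular resistance index in Wood units times m^2
#'
#' Converts a summed resistance in mmHg·s/ml to an indexed value:
#' `R_sum * (1000/60) * BSA`. One Wood unit is 1 mmHg per L/min, hence
#' the exact factor 1000/60 per mmHg·s/ml.
#'
#' @param R_sum summed bed resistance (`R_c + R_a + R_v`), mmHg·s/ml.
#' @param BSA body surface area, m^2.
#' @return Indexed resistance, Wood units·m^2; linear in both arguments.
#' @examples
#' resistance_index(0.0655 + 0.075 + 0.0492, 0.58)   # 1.83
#' @export
resistance_index <- function(R_sum, BSA) {
  stopifnot(R_sum > 0, BSA > 0)
  R_sum * (1000 / 60) * BSA
}

#' Reduce a converged cycle to clinical summary scalars
#'
#' Systolic and diastolic pressures are the extrema of the aortic-root
#' pressure `P_ao` — the Windkessel input node proximal to the
#' characteristic impedance, where a clinical arterial line sits and
#' where the three-element Windkessel is designed to reproduce arterial
#' pressure; CVP is the cycle mean of the systemic venous node
#' `P_Cv_s` (the cavopulmonary conduit). Flows are cycle means
#' converted to L/min; `Q_s` is aortic valve flow, `Q_p` pulmonary
#' artery inflow, `Q_f` fenestration flow. CI is `Q_s / BSA`. SBV is
#' the total volume across compartments (all unstressed volumes are
#' zero, so stored volume is stressed volume). The oxygen block solves
#' [oxygen_saturations()] at the cycle-mean flows; with a closed
#' fenestration SpO2 equals the pulmonary venous saturation exactly.
#'
#' @param beat a converged `fontan_beat` from [run_to_steady_state()].
#' @param params parameter bundle; defaults to the one the beat was run
#'   with.
#' @return One-row data frame of class `fontan_summary` with columns
#'   `SBP`, `DBP`, `CVP` (mmHg), `CI` (L/min/m^2), `Q_s`, `Q_p`, `Q_f`
#'   (L/min), `SpO2`, `SvO2` (percent), `SBV` (ml), `PVRI`, `SVRI`
#'   (Wood units·m^2).
#' @export
summarize_beat <- function(beat, params = attr(beat, "params")) {
  stopifnot(inherits(beat, "fontan_beat"))
  if (!isTRUE(attr(beat, "converged")))
    stop("refusing to summarize a non-converged beat", call. = FALSE)
  validate_fontan_params(params)

  # samples include both endpoints of the periodic cycle; drop the last
  # so means are over one exact period
  n <- nrow(beat)
  idx <- seq_len(n - 1)
  cyc_mean <- function(x) mean(x[idx])

  SBP <- max(beat$P_ao)
  DBP <- min(beat$P_ao)
  CVP <- cyc_mean(beat$P_Cv_s)

  ml_s_to_l_min <- 0.06
  Q_s <- cyc_mean(beat$Q_AV) * ml_s_to_l_min
  Q_p <- cyc_mean(beat$Q_pa) * ml_s_to_l_min
  Q_f <- cyc_mean(beat$Q_f) * ml_s_to_l_min
  CI <- Q_s / params$BSA

  ox <- params$oxygen
  ox$BSA <- params$BSA
  if (params$fenestration$D == 0 || Q_f <= 1e-12) {
    # no venous admixture reaches the atrium: closed fenestration, or a
    # net left-to-right shunt carrying arterial blood into the conduit.
    # Arterial saturation is then the pulmonary venous one exactly.
    k <- ox$CVO2 * ox$BSA / (ox$hb_o2_capacity * ox$Hb * ox$dl_per_l * Q_s)
    sat <- list(SaO2 = ox$S_pv_O2, SvO2 = ox$S_pv_O2 - k)
    if (sat$SvO2 <= 0)
      stop("oxygen transport infeasible at this flow", call. = FALSE)
  } else {
    sat <- oxygen_saturations(Q_s, Q_p, Q_f, ox)
  }

  SBV <- sum(beat[1, state_names()])
  PVRI <- resistance_index(params$pulmonary$R_c + params$pulmonary$R_a +
                             params$pulmonary$R_v, params$BSA)
  SVRI <- resistance_index(params$systemic$R_c + params$systemic$R_a +
                             params$systemic$R_v, params$BSA)

  structure(data.frame(SBP = SBP, DBP = DBP, CVP = CVP, CI = CI,
                       Q_s = Q_s, Q_p = Q_p, Q_f = Q_f,
                       SpO2 = 100 * sat$SaO2, SvO2 = 100 * sat$SvO2,
                       SBV = SBV, PVRI = PVRI, SVRI = SVRI),
            class = c("fontan_summary", "data.frame"))
}

#' @export
print.fontan_summary <- function(x, ...) {
  cat("Hemodynamic summary (one converged cycle)\n")
  cat(sprintf("  BP %.1f/%.1f mmHg, CVP %.1f mmHg\n", x$SBP, x$DBP, x$CVP))
  cat(sprintf("  CI %.2f L/min/m^2 (Q_s %.2f, Q_p %.2f, Q_f %.2f L/min)\n",
              x$CI, x$Q_s, x$Q_p, x$Q_f))
  cat(sprintf("  SpO2 %.1f%%, SvO2 %.1f%%, SBV %.0f ml\n",
              x$SpO2, x$SvO2, x$SBV))
  cat(sprintf("  PVRI %.2f, SVRI %.1f Wood units m^2\n", x$PVRI, x$SVRI))
  invisible(x)
}
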