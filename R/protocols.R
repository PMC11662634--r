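#' Stressed-blood-volume tuning specification
#'
#' Every protocol configuration is run at the stressed blood volume
#' that holds systolic pressure at the baseline target, searched on a
#' fixed volume grid (1-ml granularity by default).
#'
#' @param target_SBP systolic pressure target, mmHg.
#' @param step SBV grid step, ml.
#' @param max_iters maximum number of steady-state evaluations.
#' @return A list of class `tuning_spec`.
#' @export
tuning_spec <- function(target_SBP = 87.2, step = 1, max_iters = 200) {
  stopifnot(target_SBP > 0, step > 0, max_iters >= 2)
  structure(list(target_SBP = target_SBP, step = step,
                 max_iters = max_iters),
            class = "tuning_spec")
}

#' Tune stressed blood volume to the systolic-pressure target
#'
#' Searches the SBV grid `start_SBV + k * step` for the point whose
#' converged systolic pressure is closest to `spec$target_SBP`,
#' exploiting that systolic pressure is strictly increasing in SBV:
#' the bracket around the target is found with geometrically growing
#' grid steps and narrowed by bisection on the grid (the same grid
#' point a unit-step walk would reach, in far fewer runs). Ties between
#' the two bracketing grid points go to the smaller SBV. Each candidate
#' is integrated from a fresh [initialize_state()] so the result is
#' independent of the search path.
#'
#' @param params a [fontan_params()] bundle.
#' @param spec a [tuning_spec()].
#' @param start_SBV starting grid anchor, ml.
#' @param settings an [integrator_settings()].
#' @return A list of class `fontan_tuned` with elements `SBV` (ml),
#'   `beat` (the converged `fontan_beat` at that SBV), `summary`
#'   (its [summarize_beat()] row), `evals` (number of steady-state
#'   runs) and `trace` (data frame of evaluated SBV/SBP pairs).
#' @export
tune_sbv <- function(params, spec = tuning_spec(), start_SBV = 450,
                     settings = integrator_settings()) {
  validate_fontan_params(params)
  stopifnot(inherits(spec, "tuning_spec"))
  if (!is.finite(start_SBV) || start_SBV <= 0)
    stop("start_SBV must be > 0", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  trace <- list()
  evals <- 0L
  eval_sbp <- function(sbv) {
    key <- sprintf("%.9g", sbv)
    if (!is.null(cache[[key]])) return(cache[[key]])
    evals <<- evals + 1L
    if (evals > spec$max_iters) {
      tr <- do.call(rbind, trace)
      stop(paste0("SBV tuning exceeded max_iters = ", spec$max_iters,
                  "; trace:\n",
                  paste(sprintf("  SBV %.1f -> SBP %.3f", tr$SBV, tr$SBP),
                        collapse = "\n")), call. = FALSE)
    }
    beat <- run_to_steady_state(params, SBV = sbv, settings = settings)
    sbp <- max(beat$P_ao)
    trace[[length(trace) + 1L]] <<- data.frame(SBV = sbv, SBP = sbp)
    cache[[key]] <- list(sbp = sbp, beat = beat)
    cache[[key]]
  }
  target <- spec$target_SBP
  h <- spec$step
  grid_sbv <- function(k) start_SBV + k * h  # grid anchored at start_SBV

  f0 <- eval_sbp(grid_sbv(0))$sbp
  dir <- if (f0 < target) 1L else -1L

  # geometric bracketing on grid indices, then bisection; systolic
  # pressure increases with SBV, so the bracket straddles the target
  step_k <- 1L
  k_lo <- 0L; f_lo <- f0
  k_hi <- NA_integer_
  while (is.na(k_hi)) {
    k_new <- k_lo + dir * step_k
    if (grid_sbv(k_new) <= 0)
      stop("SBV tuning walked below zero volume", call. = FALSE)
    f_new <- eval_sbp(grid_sbv(k_new))$sbp
    if (dir * (f_new - f_lo) < -1e-9 * max(1, abs(f_lo)))
      stop("systolic pressure is not monotone in SBV near ",
           sprintf("%.0f ml", grid_sbv(k_new)), call. = FALSE)
    if ((f_new - target) * dir >= 0) {
      k_hi <- k_new
    } else {
      k_lo <- k_new; f_lo <- f_new
      step_k <- step_k * 2L
    }
  }
  while (abs(k_hi - k_lo) > 1L) {
    k_mid <- k_lo + as.integer((k_hi - k_lo) %/% 2L)
    f_mid <- eval_sbp(grid_sbv(k_mid))$sbp
    if ((f_mid - target) * dir >= 0) {
      k_hi <- k_mid
    } else {
      k_lo <- k_mid
    }
  }

  cand <- sort(grid_sbv(c(k_lo, k_hi)))
  errs <- vapply(cand, function(s) abs(eval_sbp(s)$sbp - target), 0)
  # tie goes to the smaller SBV
  best <- cand[order(errs, cand)][1]
  hit <- eval_sbp(best)
  structure(list(SBV = best, beat = hit$beat,
                 summary = summarize_beat(hit$beat, params),
                 evals = evals, trace = do.call(rbind, trace)),
            class = "fontan_tuned")
}

#' @export
print.fontan_tuned <- function(x, ...) {
  cat(sprintf("Tuned SBV: %.0f ml (%d steady-state runs)\n", x$SBV, x$evals))
  print(x$summary)
  invisible(x)
}

#' Scenario sweep grids
#'
#' Named sweeps over a single model parameter, each paired with a set
#' of fenestration diameters:
#' \describe{
#'   \item{diameter}{fenestration diameter 0 to 4.5 mm in 0.5-mm steps.}
#'   \item{PVR}{pulmonary arterial resistance `R_a,p` from 0.0001 to
#'     0.5251 mmHg·s/ml in steps of 0.075 (PVRI 1.11 to 6.18 Wood
#'     units·m^2); paired diameters 0, 2.0 and 2.5 mm.}
#'   \item{Ees}{ventricular end-systolic elastance 13.1 down to
#'     3.2 mmHg/ml in steps of 3.3 (systolic dysfunction).}
#'   \item{B}{ventricular stiffness constant 0.075 to 0.120 /ml in
#'     steps of 0.015 (diastolic dysfunction).}
#'   \item{SVR}{systemic arterial resistance `R_a,s` 0.8 to
#'     5.0 mmHg·s/ml in steps of 0.7 (SVRI 9.16 to 49.8).}
#' }
#' Grid values are built from exact decimal steps; derived index labels
#' (PVRI, SVRI) are computed, not enumerated.
#'
#' @param name one of `"diameter"`, `"PVR"`, `"Ees"`, `"B"`, `"SVR"`.
#' @param values optional replacement for the default grid (strictly
#'   monotone, nonempty).
#' @param diameters fenestration diameters to pair with each value, mm;
#'   ignored for the `diameter` sweep. Defaults: `c(0, 2, 2.5)` for
#'   `PVR`, `c(0, 2.5)` otherwise.
#' @return A list of class `scenario_grid`.
#' @export
scenario_grid <- function(name = c("diameter", "PVR", "Ees", "B", "SVR"),
                          values = NULL, diameters = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    diameter = list(values = seq(0, 4.5, by = 0.5), diameters = NA_real_),
    PVR = list(values = 0.0001 + 0.075 * 0:7, diameters = c(0, 2, 2.5)),
    Ees = list(values = 13.1 - 3.3 * 0:3, diameters = c(0, 2.5)),
    B = list(values = 0.075 + 0.015 * 0:3, diameters = c(0, 2.5)),
    SVR = list(values = 0.8 + 0.7 * 0:6, diameters = c(0, 2.5)))
  if (is.null(values)) values <- defaults$values
  if (is.null(diameters)) diameters <- defaults$diameters
  if (length(values) == 0 || anyNA(values))
    stop("values must be nonempty", call. = FALSE)
  d <- diff(values)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("values must be strictly monotone", call. = FALSE)
  structure(list(name = name, values = values, diameters = diameters),
            class = "scenario_grid")
}

# set the swept parameter on a cloned bundle
apply_scenario_value <- function(base, name, value) {
  p <- base
  switch(name,
         diameter = { p$fenestration$D <- value },
         PVR = { p$pulmonary$R_a <- value },
         Ees = { p$SV$E_es <- value },
         B = { p$SV$B <- value },
         SVR = { p$systemic$R_a <- value },
         stop("unknown scenario: ", name, call. = FALSE))
  validate_fontan_params(p)
  p
}

#' Run a paired fenestrated/non-fenestrated scenario sweep
#'
#' For each grid value and each fenestration diameter, clones the base
#' parameter bundle, sets the swept parameter and the diameter, tunes
#' SBV to the systolic target with [tune_sbv()], and summarizes the
#' converged cycle. The tuned SBV of one cell seeds the search of the
#' next cell in the same diameter track (the tuned result itself does
#' not depend on the seed).
#'
#' @param base a [fontan_params()] bundle (baseline).
#' @param grid a [scenario_grid()].
#' @param spec a [tuning_spec()].
#' @param settings an [integrator_settings()].
#' @param start_SBV SBV search anchor for the first cell of each
#'   diameter track, ml.
#' @return A data frame of class `fontan_sweep` with one row per
#'   (value, diameter) cell: `scenario`, `value`, `diameter`, `SBV` and
#'   all [summarize_beat()] columns.
#' @export
run_scenario <- function(base, grid, spec = tuning_spec(),
                         settings = integrator_settings(),
                         start_SBV = 450) {
  validate_fontan_params(base)
  stopifnot(inherits(grid, "scenario_grid"))
  diameters <- if (grid$name == "diameter") NA_real_ else grid$diameters
  rows <- list()
  for (d in diameters) {
    seed <- start_SBV
    for (v in grid$values) {
      p <- apply_scenario_value(base, grid$name, v)
      if (!is.na(d)) p$fenestration$D <- d
      tuned <- tryCatch(
        tune_sbv(p, spec, start_SBV = seed, settings = settings),
        error = function(e) stop(sprintf(
          "scenario %s, value %g, diameter %s: %s", grid$name, v,
          ifelse(is.na(d), "swept", format(p$fenestration$D)),
          conditionMessage(e)), call. = FALSE))
      seed <- max(tuned$SBV, spec$step)
      row <- cbind(data.frame(scenario = grid$name, value = v,
                              diameter = p$fenestration$D,
                              SBV_tuned = tuned$SBV),
                   as.data.frame(tuned$summary))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("fontan_sweep", "data.frame"),
            spec = spec, settings = settings)
}

#' Paired fenestrated vs non-fenestrated deltas at one grid value
#'
#' @param result a `fontan_sweep` from [run_scenario()].
#' @param at_value swept-parameter value at which to compare (matched
#'   within a small tolerance).
#' @param diameters length-2 vector: fenestrated diameter first,
#'   reference diameter second.
#' @return One-row data frame of deltas (fenestrated minus reference)
#'   `dCVP`, `dSBV`, `dCI`, `dSpO2`, `dDBP`, with the two matched rows
#'   attached as attributes `fenestrated` and `reference`.
#' @export
compare_fenestration <- function(result, at_value, diameters = c(2.5, 0)) {
  stopifnot(inherits(result, "fontan_sweep"), length(diameters) == 2)
  pick <- function(d) {
    i <- which(abs(result$value - at_value) < 1e-9 &
                 abs(result$diameter - d) < 1e-9)
    if (length(i) != 1)
      stop(sprintf("no unique row at value %g, diameter %g", at_value, d),
           call. = FALSE)
    result[i, ]
  }
  fen <- pick(diameters[1])
  ref <- pick(diameters[2])
  structure(data.frame(value = at_value,
                       dCVP = fen$CVP - ref$CVP,
                       dSBV = fen$SBV - ref$SBV,
                       dCI = fen$CI - ref$CI,
                       dSpO2 = fen$SpO2 - ref$SpO2,
                       dDBP = fen$DBP - ref$DBP),
            fenestrated = fen, reference = ref)
}
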