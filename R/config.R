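# Configuration documents: a YAML (or JSON) mapping in the model's
# display units (ms, bpm, mm, mmHg, mmHg*s/ml, ml/mmHg). Omitted fields
# fall back to the packaged baseline defaults; unknown keys are errors.

#' Default configuration document
#'
#' The full baseline configuration as a nested list, in display units.
#' This is the document [load_config()] merges user files over, and the
#' one `dump-defaults` writes.
#'
#' @return Nested list with sections `heart`, `valves`, `systemic`,
#'   `pulmonary`, `fenestration`, `body`, `oxygen`, `solver`, `tuning`.
#' @export
default_config <- function() {
  list(
    heart = list(
      HR_bpm = 80,
      T_c_ms = 750,
      DT_fraction = 0.02,
      SV = list(E_es = 13.1, A = 1.15, B = 0.0753, V_0 = 0, T_es_ms = 200),
      SA = list(E_es = 1.64, A = 0.197, B = 0.865, V_0 = 0, T_es_ms = 120)),
    valves = list(R_AV = 0.001, R_AVV = 0.001),
    systemic = list(R_c = 0.0984, R_a = 1.5, R_v = 0.0491,
                    C_a = 0.61, C_v = 24.2),
    pulmonary = list(R_c = 0.0655, R_a = 0.075, R_v = 0.0492,
                     C_a = 3.97, C_v = 2.52),
    fenestration = list(D_mm = 2.5),
    body = list(BSA_m2 = 0.58),
    oxygen = list(S_pv_O2 = 0.99, CVO2 = 185, Hb = 14),
    solver = list(dt_ms = 0.05, max_beats = 200, tol_ml = 1e-3),
    tuning = list(target_SBP = 87.2, step_ml = 1, max_iters = 200))
}

# recursive merge with unknown-key detection; `path` carries the field
# path for error messages
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || is.null(names(user)) && length(user))
    stop("config section '", paste(path, collapse = "."),
         "' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     c(path, nm))
    } else {
      v <- user[[nm]]
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
        stop("config field '", paste(c(path, nm), collapse = "."),
             "' must be a single finite number", call. = FALSE)
      defaults[[nm]] <- v
    }
  }
  defaults
}

# build the typed objects from a merged document
config_to_objects <- function(doc) {
  h <- doc$heart
  if (abs(h$T_c_ms - 60000 / h$HR_bpm) > 1e-6)
    stop(sprintf(
      "heart.T_c_ms (%g) inconsistent with heart.HR_bpm (%g): T_c must equal 60000/HR = %g ms",
      h$T_c_ms, h$HR_bpm, 60000 / h$HR_bpm), call. = FALSE)
  params <- fontan_params(
    SV = chamber_params(h$SV$E_es, h$SV$A, h$SV$B, h$SV$V_0, h$SV$T_es_ms),
    SA = chamber_params(h$SA$E_es, h$SA$A, h$SA$B, h$SA$V_0, h$SA$T_es_ms),
    AV = valve_params(doc$valves$R_AV),
    AVV = valve_params(doc$valves$R_AVV),
    systemic = do.call(windkessel_params, doc$systemic),
    pulmonary = do.call(windkessel_params, doc$pulmonary),
    fenestration = fenestration_params(doc$fenestration$D_mm),
    timing = timing_params(h$HR_bpm, h$DT_fraction),
    BSA = doc$body$BSA_m2,
    oxygen = oxygen_params(doc$oxygen$S_pv_O2, doc$oxygen$CVO2,
                           doc$oxygen$Hb, BSA = doc$body$BSA_m2))
  list(params = params,
       settings = integrator_settings(doc$solver$dt_ms, doc$solver$max_beats,
                                      doc$solver$tol_ml),
       tuning = tuning_spec(doc$tuning$target_SBP, doc$tuning$step_ml,
                            doc$tuning$max_iters),
       document = doc)
}

#' Load a model configuration
#'
#' Reads a YAML (or JSON — YAML is a superset) document, merges it over
#' [default_config()], validates it, and builds the typed parameter
#' bundle. An empty document yields exactly the baseline defaults.
#' Unknown keys are rejected rather than silently ignored, and
#' `heart.T_c_ms`, when given, must equal `60000 / heart.HR_bpm`.
#'
#' @param path path to a config file; or use `text`.
#' @param text config document as a string (alternative to `path`).
#' @return A list with `params` ([fontan_params()]), `settings`
#'   ([integrator_settings()]), `tuning` ([tuning_spec()]) and the
#'   merged `document`.
#' @export
load_config <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text))
    stop("supply exactly one of path or text", call. = FALSE)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
  } else {
    user <- yaml::yaml.load(text)
  }
  doc <- merge_config(default_config(), user)
  config_to_objects(doc)
}

#' Write a configuration document to YAML
#'
#' `load_config(dump_config(cfg, path))` round-trips losslessly.
#'
#' @param config a config list as returned by [load_config()], or a
#'   bare document list; `NULL` writes the packaged defaults.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config = NULL, path) {
  doc <- if (is.null(config)) default_config()
         else if (!is.null(config$document)) config$document
         else config
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Write a sweep result as CSV with a metadata header
#'
#' Writes `#`-prefixed provenance lines (package version, solver
#' settings, tuning target) followed by an RFC-4180 CSV table with at
#' least six significant digits per value.
#'
#' @param result a `fontan_sweep` or any data frame of summary rows.
#' @param path output path.
#' @param meta optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path, meta = NULL) {
  stopifnot(is.data.frame(result))
  settings <- attr(result, "settings")
  spec <- attr(result, "spec")
  hdr <- c(
    sprintf("# fontansim %s", as.character(utils::packageVersion("fontansim"))),
    if (!is.null(settings))
      sprintf("# solver: dt_ms=%g max_beats=%d tol_ml=%g",
              settings$dt, settings$max_beats, settings$tol),
    if (!is.null(spec))
      sprintf("# tuning: target_SBP=%g step_ml=%g", spec$target_SBP,
              spec$step),
    if (!is.null(meta)) sprintf("# %s: %s", names(meta), meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 8))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a sweep CSV written by [write_sweep()]
#'
#' @param path file path.
#' @return Data frame of the table rows (metadata lines skipped).
#' @export
read_sweep <- function(path) {
  read.csv(path, comment.char = "#")
}
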