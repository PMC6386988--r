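#' Default nested configuration
#'
#' The full configuration tree covering every module, with the apparatus
#' defaults: 100 x 100 x 15 mm block, 12 inclusions of 5 mm radius (3 per
#' material), 50 mm neutral sphere, 0.5 N force ceiling, 5 kHz neuron
#' integration, and the six-minute session protocol.
#'
#' @return a named nested list.
#' @export
default_config <- function() {
  mats <- default_materials()
  list(
    phantom = list(
      size_xyz = c(100, 100, 15),
      matrix_material = "DS10",
      materials = as.list(setNames(mats$stiffness_k, mats$name)),
      inclusion_materials = c("DS20", "DS30", "PDMS", "SC"),
      replicas = 3L,
      radius = 5,
      margin = 5,
      blend_width = 0,
      max_attempts = 10000L
    ),
    control = list(rho0 = 50, gain = 1, max_speed = 20,
                   workspace = c(0, 100, 0, 100)),
    encoder = list(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30, dt = 0.2,
                   force_max = 0.5, target_rate_top = 100),
    subject = list(rate_window = 0.1, change_threshold = 12,
                   reaction_latency = 0.3, refractory = 1,
                   guess_rate = 0, lapse_rate = 0, press_jitter_sd = 2,
                   baseline_windows = 5L),
    session = list(duration = 360, control_rate = 100, encoder_rate = 5000,
                   force_setpoint = 0.25, force_clamp = 0.5,
                   servo_tau = 0.05, mode = "ILS",
                   latency = list(type = "fixed", bound_s = 0.002),
                   seed = 1L),
    analysis = list(tolerances = c(5, 10, 15, 20), tolerance_mm = 10)
  )
}

merge_validate <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (!is.list(override))
    abort("config section '%s' must be a mapping", path)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    abort("unknown config key(s): %s",
          paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                 collapse = ", "))
  for (key in names(override)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "materials") {
      defaults[[key]] <- merge_validate(defaults[[key]], override[[key]],
                                        paste0(path, ".", key))
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  defaults
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, fills unspecified keys with the defaults of
#' [default_config()], rejects unknown keys by name, and instantiates every
#' module configuration so that each module's invariants are checked before
#' any simulation runs. An empty file yields the all-defaults configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a list of class `telepalp_config` with typed elements `phantom`
#'   ([phantom_config()]), `control` ([control_config()]), `encoder_params`
#'   ([izhikevich_params()]), `encoder` (raw section), `subject`
#'   ([subject_model()]), `session` ([session_config()]), `analysis`, and
#'   the merged plain list in `$raw`.
#' @export
load_config <- function(path = NULL) {
  override <- if (is.null(path)) list() else {
    if (!file.exists(path)) abort("config file not found: %s", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  raw <- merge_validate(default_config(), override)

  mats <- data.frame(name = names(raw$phantom$materials),
                     stiffness_k = unlist(raw$phantom$materials,
                                          use.names = FALSE),
                     stringsAsFactors = FALSE)
  if (any(mats$stiffness_k <= 0)) abort("material stiffness must be > 0")
  ph <- phantom_config(
    size_xyz = as.numeric(raw$phantom$size_xyz),
    matrix_material = raw$phantom$matrix_material,
    materials = mats,
    inclusion_materials = unlist(raw$phantom$inclusion_materials),
    replicas = as.integer(raw$phantom$replicas),
    radius = raw$phantom$radius,
    margin = raw$phantom$margin,
    blend_width = raw$phantom$blend_width,
    max_attempts = as.integer(raw$phantom$max_attempts)
  )
  ctl <- control_config(rho0 = raw$control$rho0, gain = raw$control$gain,
                        max_speed = raw$control$max_speed,
                        workspace = as.numeric(raw$control$workspace))
  enc <- izhikevich_params(a = raw$encoder$a, b = raw$encoder$b,
                           c = raw$encoder$c, d = raw$encoder$d,
                           v_peak = raw$encoder$v_peak, dt = raw$encoder$dt)
  subj <- do.call(subject_model, raw$subject)
  ses <- session_config(
    duration = raw$session$duration,
    control_rate = raw$session$control_rate,
    encoder_rate = raw$session$encoder_rate,
    force_setpoint = raw$session$force_setpoint,
    force_clamp = raw$session$force_clamp,
    servo_tau = raw$session$servo_tau,
    mode = raw$session$mode,
    latency = latency_model(raw$session$latency$type,
                            raw$session$latency$bound_s),
    seed = raw$session$seed
  )
  structure(list(phantom = ph, control = ctl, encoder_params = enc,
                 encoder = raw$encoder, subject = subj, session = ses,
                 analysis = raw$analysis, raw = raw),
            class = "telepalp_config")
}

#' Save a configuration as YAML
#'
#' Writes the merged plain configuration so that a save/load round trip is
#' idempotent.
#'
#' @param cfg a `telepalp_config` (or a plain nested list).
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "telepalp_config")) cfg$raw else cfg
  yaml::write_yaml(raw, path)
  invisible(path)
}
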