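#' Latency model
#'
#' The communication channel between the tactile and haptic sub-systems is
#' modelled as a bounded per-sample delay: `"fixed"` delays every sample by
#' `bound_s`; `"jittered"` draws each delay uniformly from `[0, bound_s]`
#' and enforces order preservation. The default bound is the 15 ms maximum
#' latency of the transport.
#'
#' @param type `"fixed"` or `"jittered"`.
#' @param bound_s delay bound, s (default 0.015).
#' @return a list of class `telepalp_latency`.
#' @export
latency_model <- function(type = c("fixed", "jittered"), bound_s = 0.015) {
  type <- match.arg(type)
  check_scalar_num(bound_s, "bound_s", 0)
  structure(list(type = type, bound_s = bound_s),
            class = "telepalp_latency")
}

#' Delay a time series through the latency channel
#'
#' Each output sample takes the input value at `t - d(t)` with `d(t)` drawn
#' from the latency model and clamped to `[0, bound_s]`; the effective read
#' times are made non-decreasing (a late packet never overtakes an earlier
#' one) and values before the first input are held at the first value.
#'
#' @param series data.frame whose first column is time (s) and second the
#'   value.
#' @param lat a [latency_model()].
#' @param seed seed for the jitter stream.
#' @return a data.frame of the same shape with the delayed values.
#' @export
apply_latency <- function(series, lat = latency_model(), seed = 1L) {
  t <- series[[1]]
  v <- series[[2]]
  if (lat$bound_s == 0) return(series)
  d <- if (lat$type == "fixed") {
    rep(lat$bound_s, length(t))
  } else {
    set.seed(derive_seed(seed, "latency-jitter"))
    runif(length(t), 0, lat$bound_s)
  }
  read_t <- cummax(t - d)  # order-preserving effective read times
  out <- series
  out[[2]] <- interp_series(t, v, read_t)
  out
}

#' Session configuration
#'
#' @param duration session length, s (default 360, the six-minute protocol).
#' @param control_rate gesture/stage loop rate, Hz (default 100).
#' @param encoder_rate neuron integration rate, Hz (fixed at 5000 by the
#'   default neuron step).
#' @param force_setpoint palpation force the depth servo tracks, N; must not
#'   exceed the 0.5 N protective clamp (default 0.25, keeping stiffness
#'   transients below the clamp).
#' @param force_clamp protective force ceiling, N (0.5).
#' @param servo_tau time constant of the first-order depth servo, s
#'   (default 0.05).
#' @param mode `"ILS"` (in line of sight, platform local) or `"NILS"`
#'   (remote); selects the default latency profile: a short fixed 2 ms delay
#'   for ILS, jittered delays bounded by 15 ms for NILS.
#' @param latency optional explicit [latency_model()] overriding the mode
#'   default.
#' @param seed master seed; all sub-streams derive from it.
#' @return a list of class `telepalp_session_config`.
#' @export
session_config <- function(duration = 360, control_rate = 100,
                           encoder_rate = 5000, force_setpoint = 0.25,
                           force_clamp = 0.5, servo_tau = 0.05,
                           mode = c("ILS", "NILS"), latency = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  check_scalar_num(duration, "duration", 0, strict_lower = TRUE)
  check_scalar_num(control_rate, "control_rate", 0, strict_lower = TRUE)
  check_scalar_num(force_setpoint, "force_setpoint", 0, upper = force_clamp,
                   strict_lower = TRUE)
  check_scalar_num(servo_tau, "servo_tau", 0, strict_lower = TRUE)
  if (is.null(latency))
    latency <- if (mode == "ILS") latency_model("fixed", 0.002)
               else latency_model("jittered", 0.015)
  structure(list(duration = duration, control_rate = control_rate,
                 encoder_rate = encoder_rate,
                 force_setpoint = force_setpoint, force_clamp = force_clamp,
                 servo_tau = servo_tau, mode = mode, latency = latency,
                 seed = as.integer(seed)),
            class = "telepalp_session_config")
}

#' Scripted hand-trajectory sources
#'
#' Builds a `hand_source(t, stage_pos)` closure for [run_session()]:
#'
#' * `"raster"`: a serpentine sweep over `params$x_range` x `params$y_range`
#'   with line pitch `params$pitch` (mm) at `params$speed` (mm/s). The hand
#'   pursues a carrot moving along the pattern: the displacement direction
#'   points from the current stage position to the carrot and its magnitude
#'   is chosen so the control law commands the pursuit velocity.
#' * `"waypoints"`: the same pursuit over `params$points` (n x 2 matrix); an
#'   empty set keeps the hand at the sensor centre (inside the dead zone).
#' * `"replay"`: replays recorded hand samples (`params$hand`, a data.frame
#'   `t_s`, `x_mm`, `y_mm`, `z_mm`, or `params$file` pointing at such a
#'   CSV), interpolated at the requested times.
#'
#' @param kind `"raster"`, `"waypoints"` or `"replay"`.
#' @param params list of pattern parameters (see above).
#' @param control_cfg the [control_config()] the session will use (needed to
#'   invert the gesture law for pursuit).
#' @return a function `(t, stage_pos) -> hand position` (3-vector, mm).
#' @export
make_trajectory <- function(kind = c("raster", "waypoints", "replay"),
                            params = list(),
                            control_cfg = control_config()) {
  kind <- match.arg(kind)
  if (kind == "replay") {
    hand <- params$hand
    if (is.null(hand)) hand <- read.csv(params$file)
    return(function(t, stage_pos) {
      c(interp_series(hand$t_s, hand$x_mm, t),
        interp_series(hand$t_s, hand$y_mm, t),
        interp_series(hand$t_s, hand$z_mm, t))
    })
  }
  pts <- if (kind == "raster") {
    xr <- params$x_range %||% c(10, 90)
    yr <- params$y_range %||% c(10, 90)
    pitch <- params$pitch %||% 10
    ys <- seq(yr[1], yr[2], by = pitch)
    do.call(rbind, lapply(seq_along(ys), function(i) {
      if (i %% 2 == 1) rbind(c(xr[1], ys[i]), c(xr[2], ys[i]))
      else rbind(c(xr[2], ys[i]), c(xr[1], ys[i]))
    }))
  } else {
    p <- params$points
    if (is.null(p) || !NROW(p)) matrix(numeric(0), ncol = 2)
    else as.matrix(p)
  }
  if (!nrow(pts)) return(function(t, stage_pos) c(0, 0, 0))
  ws <- control_cfg$workspace
  if (any(pts[, 1] < ws[1] | pts[, 1] > ws[2] |
          pts[, 2] < ws[3] | pts[, 2] > ws[4]))
    abort("trajectory pattern exceeds the workspace")
  speed <- params$speed %||% 10
  kp <- params$kp %||% 5            # pursuit gain, 1/s
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  cum_len <- c(0, cumsum(seg_len))
  total <- cum_len[length(cum_len)]
  carrot_at <- function(s) {
    s <- min(max(s, 0), total)
    i <- findInterval(s, cum_len, rightmost.closed = TRUE)
    i <- min(i, nrow(pts) - 1L)
    f <- if (seg_len[i] > 0) (s - cum_len[i]) / seg_len[i] else 0
    pts[i, ] + f * seg[i, ]
  }
  function(t, stage_pos) {
    carrot <- carrot_at(speed * t)
    err <- carrot - stage_pos
    dist <- sqrt(sum(err^2))
    v_des <- min(kp * dist, control_cfg$max_speed)
    if (dist < 1e-9 || v_des <= 0) return(c(0, 0, 0))
    # invert the gesture law: displacement rho0 + v/gain along the error
    rho <- control_cfg$rho0 + v_des / control_cfg$gain
    c(rho * err / dist, 0)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a complete simulated tele-palpation session
#'
#' The loop, at `control_rate`: the hand source yields a hand sample, the
#' gesture law converts it to a stage velocity, the stage integrates within
#' the workspace, and a first-order depth servo drives the indentation depth
#' toward the depth at which the local stiffness yields `force_setpoint`.
#' The measured force (clamped at the protective 0.5 N ceiling) passes
#' through the latency channel, is resampled to the 5 kHz neuron rate,
#' encoded into spikes, and handed to the virtual subject, which emits
#' key-press responses. Identical `(configs, seed)` reproduce the log
#' exactly.
#'
#' @param phantom a `telepalp_phantom`.
#' @param subject a [subject_model()], or `NULL` to skip response
#'   generation.
#' @param control_cfg a [control_config()]; its workspace must lie within
#'   the phantom footprint.
#' @param encoder_params an [izhikevich_params()].
#' @param encoder_cal an [encoder_calibration()] (see [calibrate_gain()]).
#' @param session_cfg a [session_config()].
#' @param hand_source a `function(t, stage_pos)` (see [make_trajectory()]).
#' @return an object of class `telepalp_session`: list with `config`,
#'   `hand`, `stage`, `force` (raw, clamped and delayed force at control
#'   rate), `spikes` (a [spike_train()]), `responses`.
#' @export
run_session <- function(phantom, subject = subject_model(),
                        control_cfg = control_config(),
                        encoder_params = izhikevich_params(),
                        encoder_cal,
                        session_cfg = session_config(),
                        hand_source = make_trajectory("raster",
                                                      control_cfg = control_cfg)) {
  ws <- control_cfg$workspace
  if (ws[1] < 0 || ws[3] < 0 || ws[2] > phantom$size_xyz[1] ||
      ws[4] > phantom$size_xyz[2])
    abort("workspace exceeds the phantom footprint")
  enc_rate <- 1000 / encoder_params$dt
  if (abs(session_cfg$encoder_rate - enc_rate) > 1e-9)
    abort("session encoder_rate (%g Hz) does not match the neuron step (%g Hz)",
          session_cfg$encoder_rate, enc_rate)

  dt <- 1 / session_cfg$control_rate
  n <- round(session_cfg$duration * session_cfg$control_rate)
  t <- seq_len(n) * dt
  servo_alpha <- 1 - exp(-dt / session_cfg$servo_tau)

  pos <- c(mean(ws[1:2]), mean(ws[3:4]))
  depth <- 0
  hand_log <- matrix(0, n, 3)
  stage_log <- matrix(0, n, 4)
  force_log <- matrix(0, n, 3)  # depth, raw Fz, clamped Fz
  for (i in seq_len(n)) {
    hand <- hand_source(t[i], pos)
    vel <- gesture_to_velocity(hand, control_cfg)
    pos <- integrate_stage(pos, vel, dt, control_cfg)
    k <- local_stiffness(phantom, pos)
    depth_target <- session_cfg$force_setpoint / k
    depth <- depth + (depth_target - depth) * servo_alpha
    fz_raw <- contact_force(k, depth)
    fz <- min(fz_raw, session_cfg$force_clamp)
    hand_log[i, ] <- hand
    stage_log[i, ] <- c(pos, vel)
    force_log[i, ] <- c(depth, fz_raw, fz)
  }

  force <- data.frame(t_s = t, depth_mm = force_log[, 1],
                      fz_raw_N = force_log[, 2], fz_N = force_log[, 3])
  delayed <- apply_latency(force[c("t_s", "fz_N")], session_cfg$latency,
                           seed = derive_seed(session_cfg$seed, "latency"))
  force$fz_delayed_N <- delayed$fz_N

  # resample the delayed force to the neuron integration grid
  t_enc <- seq_len(round(session_cfg$duration * enc_rate)) / enc_rate
  f_enc <- interp_series(force$t_s, force$fz_delayed_N, t_enc)
  spikes <- encode_force(f_enc, encoder_cal, encoder_params)

  stage <- data.frame(t_s = t, x_mm = stage_log[, 1], y_mm = stage_log[, 2],
                      vx = stage_log[, 3], vy = stage_log[, 4])
  responses <- NULL
  if (!is.null(subject)) {
    det <- detect_rate_changes(spikes, subject)
    det <- det[det <= session_cfg$duration]
    responses <- emit_responses(det, stage, subject,
                                seed = derive_seed(session_cfg$seed,
                                                   "subject"))
  }

  structure(list(
    config = list(control = unclass(control_cfg),
                  encoder_params = unclass(encoder_params),
                  encoder_cal = unclass(encoder_cal),
                  session = c(unclass(session_cfg)[setdiff(
                    names(session_cfg), "latency")],
                    list(latency = unclass(session_cfg$latency))),
                  subject = if (!is.null(subject)) unclass(subject)),
    hand = data.frame(t_s = t, x_mm = hand_log[, 1], y_mm = hand_log[, 2],
                      z_mm = hand_log[, 3]),
    stage = stage,
    force = force,
    spikes = spikes,
    responses = responses
  ), class = "telepalp_session")
}

#' @export
print.telepalp_session <- function(x, ...) {
  cat(sprintf(
    "<telepalp_session> %s, %.0f s: %d spikes, %s responses, max Fz %.3f N\n",
    x$config$session$mode, x$config$session$duration, length(x$spikes$times),
    if (is.null(x$responses)) "no" else nrow(x$responses),
    max(x$force$fz_N)))
  invisible(x)
}

#' Write / read a session log directory
#'
#' The log is a directory holding `config.json` plus CSV streams (`hand`,
#' `stage`, `force`, `responses`) and the spike train (`spikes.txt` with its
#' JSON sidecar). Writing is deterministic: the same log always produces
#' byte-identical files.
#'
#' @param log a `telepalp_session`.
#' @param dir directory path (created if missing).
#' @export
write_session_log <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                  scientific = FALSE) else col)
    df
  }
  jsonlite::write_json(log$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(num(log$hand), file.path(dir, "hand.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(num(log$stage), file.path(dir, "stage.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(num(log$force), file.path(dir, "force.csv"), row.names = FALSE,
            quote = FALSE)
  write_spiketrain(log$spikes, file.path(dir, "spikes.txt"))
  if (!is.null(log$responses))
    write.csv(num(log$responses), file.path(dir, "responses.csv"),
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  resp_file <- file.path(dir, "responses.csv")
  structure(list(
    config = cfg,
    hand = read.csv(file.path(dir, "hand.csv")),
    stage = read.csv(file.path(dir, "stage.csv")),
    force = read.csv(file.path(dir, "force.csv")),
    spikes = read_spiketrain(file.path(dir, "spikes.txt")),
    responses = if (file.exists(resp_file)) read.csv(resp_file)
  ), class = "telepalp_session")
}
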