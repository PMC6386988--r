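#' Izhikevich neuron parameters
#'
#' The two-variable spiking model `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`,
#' `du/dt = a (b v - u)`, with the after-spike reset `v <- c`, `u <- u + d`
#' once `v` reaches `v_peak`. Defaults are the canonical regular-spiking
#' cortical parameterization; the integration step of 0.2 ms corresponds to
#' the 5 kHz Euler discretization used by the feedback chain.
#'
#' @param a recovery time scale (default 0.02).
#' @param b recovery sensitivity to `v` (default 0.2).
#' @param c after-spike reset of `v`, mV (default -65).
#' @param d after-spike increment of `u` (default 8).
#' @param v_peak spike cutoff, mV (default 30).
#' @param dt Euler step, ms (default 0.2, i.e. 5 kHz).
#' @return a list of class `telepalp_izh_params`.
#' @export
izhikevich_params <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                              v_peak = 30, dt = 0.2) {
  check_scalar_num(dt, "dt", 0, strict_lower = TRUE)
  if (v_peak <= c) abort("v_peak must exceed the reset potential c")
  structure(list(a = a, b = b, c = c, d = d, v_peak = v_peak, dt = dt),
            class = "telepalp_izh_params")
}

#' Resting state of the neuron
#'
#' The quiescent state used to start every integration: `v = c`,
#' `u = b * c`.
#'
#' @param p an [izhikevich_params()].
#' @return list with `v` (mV) and `u`.
#' @export
neuron_rest <- function(p = izhikevich_params()) {
  list(v = p$c, u = p$b * p$c)
}

#' One Euler step of the neuron
#'
#' Advances the membrane/recovery state by one step of size `p$dt` under
#' input current `I`; reports whether the peak-and-reset fired during the
#' step. Deterministic. Mostly useful for inspection; bulk integration goes
#' through the compiled path used by [encode_force()].
#'
#' @param state list with `v`, `u` (see [neuron_rest()]).
#' @param I input current, model units.
#' @param p an [izhikevich_params()].
#' @return list with `state` (new `v`, `u`) and logical `spiked`.
#' @export
izhikevich_step <- function(state, I, p = izhikevich_params()) {
  res <- .izh_run_cpp(I, p$a, p$b, p$c, p$d, p$v_peak, p$dt,
                      state$v, state$u)
  list(state = list(v = res$v, u = res$u),
       spiked = length(res$spike_steps) > 0)
}

# Integrate over a current series; returns spike step indices and final state.
izh_run <- function(I_series, p, state = neuron_rest(p)) {
  .izh_run_cpp(I_series, p$a, p$b, p$c, p$d, p$v_peak, p$dt,
               state$v, state$u)
}

#' Encoder calibration
#'
#' Affine force-to-current mapping `I = input_offset + input_gain * F` used
#' to drive the neuron. `force_max` records the force (N) the calibration
#' was designed for (the protective threshold of the platform, 0.5 N).
#'
#' @param input_gain current units per N (> 0).
#' @param input_offset current units at zero force (default 0, i.e. no
#'   spontaneous firing).
#' @param force_max calibrated force range ceiling, N (default 0.5).
#' @return a list of class `telepalp_encoder_cal`.
#' @export
encoder_calibration <- function(input_gain, input_offset = 0,
                                force_max = 0.5) {
  check_scalar_num(input_gain, "input_gain", 0, strict_lower = TRUE)
  check_scalar_num(force_max, "force_max", 0, strict_lower = TRUE)
  structure(list(input_gain = input_gain, input_offset = input_offset,
                 force_max = force_max),
            class = "telepalp_encoder_cal")
}

#' Spike train container
#'
#' @param times strictly increasing spike times, s.
#' @param duration total duration, s.
#' @return a list of class `telepalp_spiketrain`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (length(times) && (is.unsorted(times, strictly = TRUE) ||
                        times[1] < 0 || times[length(times)] > duration))
    abort("spike times must be strictly increasing within [0, duration]")
  structure(list(times = times, duration = duration),
            class = "telepalp_spiketrain")
}

#' @export
print.telepalp_spiketrain <- function(x, ...) {
  cat(sprintf("<telepalp_spiketrain> %d spikes over %.3f s (mean rate %.1f Hz)\n",
              length(x$times), x$duration,
              if (x$duration > 0) length(x$times) / x$duration else 0))
  invisible(x)
}

#' Encode a force series into a spike train
#'
#' Drives the Euler-integrated neuron with `I(t) = input_offset +
#' input_gain * F(t)`, one force sample per integration step. The series
#' must therefore be sampled at `1000 / p$dt` Hz (5 kHz at the default
#' step).
#'
#' @param force_series numeric vector of normal forces, N, uniformly sampled.
#' @param cal an [encoder_calibration()].
#' @param p an [izhikevich_params()].
#' @param sample_rate sampling rate of `force_series`, Hz; must match the
#'   integration rate `1000 / p$dt`.
#' @return a [spike_train()].
#' @export
encode_force <- function(force_series, cal, p = izhikevich_params(),
                         sample_rate = 1000 / p$dt) {
  if (abs(sample_rate - 1000 / p$dt) > 1e-9 * sample_rate)
    abort("force series sampled at %g Hz but the neuron integrates at %g Hz",
          sample_rate, 1000 / p$dt)
  I <- cal$input_offset + cal$input_gain * force_series
  res <- izh_run(I, p)
  dt_s <- p$dt / 1000
  spike_train(res$spike_steps * dt_s, length(force_series) * dt_s)
}

#' Steady-state f-I curve
#'
#' Simulates the neuron at each constant input current, discards a settling
#' window, and reports the firing rate over the measurement window. The
#' monotone region of this curve defines the usable encoding range.
#'
#' @param p an [izhikevich_params()].
#' @param I_grid input currents to probe.
#' @param settle_s settling window discarded before counting, s.
#' @param measure_s measurement window, s.
#' @return data.frame with columns `I` and `rate_hz`.
#' @export
compute_fI_curve <- function(p = izhikevich_params(),
                             I_grid = seq(0, 30, by = 1),
                             settle_s = 0.5, measure_s = 1) {
  steps_settle <- round(settle_s * 1000 / p$dt)
  steps_measure <- round(measure_s * 1000 / p$dt)
  rate <- vapply(I_grid, function(I) {
    res <- izh_run(rep(I, steps_settle + steps_measure), p)
    sum(res$spike_steps > steps_settle) / measure_s
  }, numeric(1))
  data.frame(I = I_grid, rate_hz = rate)
}

#' Calibrate the force-to-current gain
#'
#' Chooses `input_gain` so that the calibrated force ceiling `force_max`
#' maps to an input current whose steady-state firing rate equals the top of
#' `target_rate_range`, while the whole interval `[0, force_max]` stays
#' inside the monotone (pre-saturation) region of the f-I curve. The gain is
#' found by probing the f-I curve on a coarse grid, restricting to its
#' longest monotone prefix, and refining the target current by bisection on
#' simulated rates.
#'
#' @param p an [izhikevich_params()].
#' @param force_max force ceiling, N (default 0.5).
#' @param target_rate_range `c(low, high)` firing rates, Hz; only the top is
#'   matched (default `c(0, 100)`).
#' @param I_max largest current probed (default 100).
#' @return an [encoder_calibration()] with attribute `rate_at_force_max`.
#' @export
calibrate_gain <- function(p = izhikevich_params(), force_max = 0.5,
                           target_rate_range = c(0, 100), I_max = 100) {
  target_top <- max(target_rate_range)
  check_scalar_num(target_top, "target_rate_range top", 0,
                   strict_lower = TRUE)
  fi <- compute_fI_curve(p, I_grid = seq(0, I_max, length.out = 31))
  # longest monotone non-decreasing prefix = usable encoding region
  drops <- which(diff(fi$rate_hz) < 0)
  knee <- if (length(drops)) drops[1] else nrow(fi)
  usable <- fi[seq_len(knee), ]
  if (max(usable$rate_hz) < target_top)
    abort(paste0("target rate %g Hz is not attainable in the monotone f-I ",
                 "region (max %g Hz at I = %g)"), target_top,
          max(usable$rate_hz), usable$I[which.max(usable$rate_hz)])
  # bracket then bisect on the simulated steady-state rate
  hi <- usable$I[which(usable$rate_hz >= target_top)[1]]
  lo <- max(usable$I[usable$rate_hz < target_top], 0)
  rate_at <- function(I) {
    res <- compute_fI_curve(p, I_grid = I)
    res$rate_hz
  }
  for (it in seq_len(30)) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) >= target_top) hi <- mid else lo <- mid
    if (hi - lo < 1e-3) break
  }
  I_star <- hi
  cal <- encoder_calibration(input_gain = I_star / force_max,
                             input_offset = 0, force_max = force_max)
  attr(cal, "rate_at_force_max") <- rate_at(I_star)
  cal
}

#' Piezo driver actuation settings
#'
#' Electrical settings of the analog piezoelectric driver stage: amplifier
#' gain, peak-to-peak drive voltage, offset voltage, and the width of the
#' pulse synthesised per spike.
#'
#' @param gain_db amplifier gain, dB (default 40.7).
#' @param vpp peak-to-peak voltage, V (default 200).
#' @param offset_v offset voltage, V (default 105).
#' @param pulse_width pulse width per spike, ms (default 1).
#' @return a list of class `telepalp_actuation`.
#' @export
actuation_config <- function(gain_db = 40.7, vpp = 200, offset_v = 105,
                             pulse_width = 1) {
  check_scalar_num(vpp, "vpp", 0, strict_lower = TRUE)
  check_scalar_num(pulse_width, "pulse_width", 0, strict_lower = TRUE)
  structure(list(gain_db = gain_db, vpp = vpp, offset_v = offset_v,
                 pulse_width = pulse_width),
            class = "telepalp_actuation")
}

#' Synthesise the driver waveform from a spike train
#'
#' Each spike becomes one biphasic square pulse about the offset voltage:
#' `+vpp/2` for the first half of `pulse_width`, `-vpp/2` for the second
#' half, so a single spike produces the full peak-to-peak excursion. The
#' baseline sits at `offset_v`. Overlapping pulses are summed and clipped to
#' `[offset_v - vpp/2, offset_v + vpp/2]`; the number of clipped samples is
#' attached as attribute `n_clipped`.
#'
#' @param train a [spike_train()].
#' @param a an [actuation_config()].
#' @param sample_rate output sampling rate, Hz; must resolve the pulse
#'   (`sample_rate >= 2 / pulse_width`).
#' @return numeric vector of voltage samples spanning the train duration.
#' @export
spikes_to_waveform <- function(train, a = actuation_config(),
                               sample_rate = 10000) {
  pw_s <- a$pulse_width / 1000
  if (sample_rate < 2 / pw_s)
    abort("sample_rate %g Hz cannot resolve a %g ms pulse", sample_rate,
          a$pulse_width)
  n <- max(1L, ceiling(train$duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  excursion <- numeric(n)
  for (ts in train$times) {
    phase <- t - ts
    excursion <- excursion +
      (a$vpp / 2) * ((phase >= 0 & phase < pw_s / 2) -
                     (phase >= pw_s / 2 & phase < pw_s))
  }
  clipped <- abs(excursion) > a$vpp / 2
  excursion[clipped] <- sign(excursion[clipped]) * a$vpp / 2
  structure(a$offset_v + excursion, n_clipped = sum(clipped))
}

#' Write / read a spike train
#'
#' Spike times as a single-column text file (seconds, one per line), with a
#' JSON sidecar `<path>.json` holding the duration and any parameters.
#'
#' @param train a [spike_train()].
#' @param path file path for the spike times.
#' @param params optional list stored in the sidecar.
#' @export
write_spiketrain <- function(train, path, params = NULL) {
  writeLines(format(train$times, digits = 15, trim = TRUE, scientific = FALSE),
             path)
  jsonlite::write_json(list(duration = train$duration, params = params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spiketrain
#' @export
read_spiketrain <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(path)
  times <- if (length(lines)) as.numeric(lines) else numeric(0)
  spike_train(times, side$duration)
}
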