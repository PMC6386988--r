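#' Virtual subject model
#'
#' A configurable stand-in for a human participant. The detector estimates
#' the firing rate in a sliding window and presses a key whenever the rate
#' departs from a running baseline (median of the preceding `baseline_windows`
#' windows) by more than `change_threshold`; presses are separated by at
#' least `refractory` seconds and delayed by `reaction_latency`. The recorded
#' press position scatters isotropically around the true stage position with
#' SD `press_jitter_sd`. `guess_rate` and `lapse_rate` are the psychometric
#' floor/ceiling parameters used by the direct response generator.
#'
#' @param rate_window sliding-window length for rate estimation, s.
#' @param change_threshold rate departure that triggers a press, Hz.
#' @param reaction_latency press delay after detection, s.
#' @param refractory minimum gap between presses, s.
#' @param guess_rate psychometric guess rate (gamma), in `[0, 1)`.
#' @param lapse_rate psychometric lapse rate (lambda), in `[0, 1)`.
#' @param press_jitter_sd spatial scatter of the press position, mm.
#' @param baseline_windows number of past windows whose median rate forms the
#'   running baseline (default 5).
#' @return a list of class `telepalp_subject`.
#' @export
subject_model <- function(rate_window = 0.1, change_threshold = 12,
                          reaction_latency = 0.3, refractory = 1,
                          guess_rate = 0, lapse_rate = 0,
                          press_jitter_sd = 2, baseline_windows = 5L) {
  check_scalar_num(rate_window, "rate_window", 0, strict_lower = TRUE)
  check_scalar_num(refractory, "refractory", 0, strict_lower = TRUE)
  check_scalar_num(guess_rate, "guess_rate", 0)
  check_scalar_num(lapse_rate, "lapse_rate", 0)
  if (guess_rate + lapse_rate >= 1)
    abort("guess_rate + lapse_rate must be < 1")
  structure(list(rate_window = rate_window,
                 change_threshold = change_threshold,
                 reaction_latency = reaction_latency,
                 refractory = refractory,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 press_jitter_sd = press_jitter_sd,
                 baseline_windows = as.integer(baseline_windows)),
            class = "telepalp_subject")
}

#' Detect firing-rate changes in a spike train
#'
#' Slides a window of length `m$rate_window` (stride = 1/4 window) along the
#' train, estimating the rate as spike count / window. The baseline is the
#' median rate over the preceding `m$baseline_windows` full windows; a
#' detection fires when `|rate - baseline| > m$change_threshold`, after which
#' the detector is refractory for `m$refractory` seconds. Reported times
#' include the reaction latency.
#'
#' @param train a [spike_train()].
#' @param m a [subject_model()].
#' @return numeric vector of detection times, s.
#' @export
detect_rate_changes <- function(train, m = subject_model()) {
  w <- m$rate_window
  stride <- w / 4
  if (train$duration < w * (m$baseline_windows + 1)) return(numeric(0))
  t_end <- seq(w * (m$baseline_windows + 1), train$duration, by = stride)
  rate_in <- function(from, to)
    sum(train$times > from & train$times <= to) / (to - from)
  detections <- numeric(0)
  last <- -Inf
  for (te in t_end) {
    if (te - last < m$refractory) next
    rate <- rate_in(te - w, te)
    base_ends <- te - w - w * (seq_len(m$baseline_windows) - 1)
    baseline <- median(vapply(base_ends, function(be) rate_in(be - w, be),
                              numeric(1)))
    if (abs(rate - baseline) > m$change_threshold) {
      detections <- c(detections, te)
      last <- te
    }
  }
  detections + m$reaction_latency
}

#' Convert detections into key-press response events
#'
#' Each detection becomes a response stamped with the stage position at the
#' detection time (linear interpolation of the stage log) plus isotropic
#' Gaussian jitter of SD `m$press_jitter_sd`, emulating the imprecision of
#' where the press is recorded relative to the probe.
#'
#' @param detections detection times, s.
#' @param stage_log data.frame with `t_s`, `x_mm`, `y_mm` covering the
#'   detection times.
#' @param m a [subject_model()].
#' @param seed seed for the jitter stream.
#' @return data.frame `t_s`, `x_mm`, `y_mm` (one row per press).
#' @export
emit_responses <- function(detections, stage_log, m = subject_model(),
                           seed = 1L) {
  if (!length(detections))
    return(data.frame(t_s = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0)))
  if (max(detections) > max(stage_log$t_s) + 1e-9 ||
      min(detections) < min(stage_log$t_s) - 1e-9)
    abort("stage log does not cover all detection times")
  x <- interp_series(stage_log$t_s, stage_log$x_mm, detections)
  y <- interp_series(stage_log$t_s, stage_log$y_mm, detections)
  set.seed(derive_seed(seed, "press-jitter"))
  n <- length(detections)
  data.frame(t_s = detections,
             x_mm = x + rnorm(n, sd = m$press_jitter_sd),
             y_mm = y + rnorm(n, sd = m$press_jitter_sd))
}

#' Psychometric detection probability
#'
#' The probability of a correct detection at stiffness `x` under the
#' logistic psychometric function with threshold `a_thr` and scale
#' `b_scale`, lifted by the guess rate and lowered by the lapse rate:
#' `P = gamma + (1 - gamma - lambda) * G(x)`, where
#' `G(x) = 1 / (1 + exp(-(x - a_thr) / b_scale))`.
#'
#' @param x stiffness, N/mm (vectorised).
#' @param a_thr perceptual threshold, N/mm.
#' @param b_scale scale parameter, N/mm (> 0).
#' @param guess_rate,lapse_rate floor/ceiling parameters.
#' @return detection probability in `[0, 1]`.
#' @export
psychometric_prob <- function(x, a_thr, b_scale, guess_rate = 0,
                              lapse_rate = 0) {
  check_scalar_num(b_scale, "b_scale", 0, strict_lower = TRUE)
  guess_rate + (1 - guess_rate - lapse_rate) *
    plogis((x - a_thr) / b_scale)
}

#' Draw Bernoulli detection responses from the psychometric model
#'
#' @inheritParams psychometric_prob
#' @param seed seed for the Bernoulli stream.
#' @return logical vector of detections, one per element of `x`.
#' @export
psychometric_response <- function(x, a_thr, b_scale, guess_rate = 0,
                                  lapse_rate = 0, seed = 1L) {
  p <- psychometric_prob(x, a_thr, b_scale, guess_rate, lapse_rate)
  set.seed(derive_seed(seed, "psychometric-response"))
  rbinom(length(x), 1, p) == 1
}

#' Write / read response events
#'
#' CSV with columns `t_s`, `x_mm`, `y_mm`; the same schema serves virtual
#' and replayed real sessions.
#'
#' @param responses data.frame of responses.
#' @param file file path.
#' @export
write_responses <- function(responses, file) {
  write.csv(responses[c("t_s", "x_mm", "y_mm")], file, row.names = FALSE,
            quote = FALSE)
  invisible(file)
}

#' @rdname write_responses
#' @export
read_responses <- function(file) read.csv(file)
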