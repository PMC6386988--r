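# Independent oracles used across the suite. These deliberately avoid the
# package's compiled integration path and its fitting routines.

# Plain-R forward-Euler integration of the spiking neuron; returns the spike
# count. Used as the fine-step reference for the 5 kHz discretization.
r_izh_spike_count <- function(I_const, duration_s, dt_ms,
                              a = 0.02, b = 0.2, c = -65, d = 8,
                              v_peak = 30) {
  n <- round(duration_s * 1000 / dt_ms)
  v <- c
  u <- b * c
  count <- 0L
  for (i in seq_len(n)) {
    vn <- v + dt_ms * (0.04 * v^2 + 5 * v + 140 - u + I_const)
    un <- u + dt_ms * a * (b * v - u)
    if (vn >= v_peak) {
      vn <- c
      un <- un + d
      count <- count + 1L
    }
    v <- vn
    u <- un
  }
  count
}

# Closed-form least-squares slope of y on x (the stiffness estimator).
ls_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Brute-force grid search minimising the residual sum of squares of the
# logistic CDF fit; confirms the least-squares minimum found by fit_cdf.
grid_fit_cdf <- function(x, r, a_grid, b_grid) {
  best <- c(a = NA, b = NA, rss = Inf)
  for (a in a_grid) for (b in b_grid) {
    rss <- sum((r - 1 / (1 + exp(-(x - a) / b)))^2)
    if (rss < best["rss"]) best <- c(a = a, b = b, rss = rss)
  }
  best
}

# A regular spike train at a given rate, useful for detector tests.
regular_train <- function(rate_hz, duration_s, t0 = 0) {
  spike_train(seq(t0 + 1 / rate_hz, duration_s, by = 1 / rate_hz),
              duration_s)
}

# A phantom with one SC inclusion at a chosen centre, built from the
# generator then repositioned (layout fields are plain data).
single_inclusion_phantom <- function(center = c(50, 50), material = "SC") {
  ph <- generate_phantom(phantom_config(inclusion_materials = material,
                                        replicas = 1L), seed = 1)
  ph$inclusions$x <- center[1]
  ph$inclusions$y <- center[2]
  ph
}

# Shared calibrated encoder (computed once per test run).
cached_cal <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- calibrate_gain()
    cal
  }
})
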