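test_that("latency channel delays, preserves order and respects its bound", {
  t <- seq(0.001, 2, by = 0.001)
  ramp <- data.frame(t_s = t, v = t)
  expect_identical(apply_latency(ramp, latency_model("fixed", 0)), ramp)

  del <- apply_latency(ramp, latency_model("fixed", 0.015))
  lag <- t - del$v
  expect_equal(max(abs(lag[t > 0.1] - 0.015)), 0, tolerance = 1e-9)

  # cross-correlation of a delayed sinusoid peaks at the 15 ms lag
  sig <- data.frame(t_s = t, v = sin(2 * pi * 3 * t))
  dsig <- apply_latency(sig, latency_model("fixed", 0.015))
  lags <- 0:30
  cc <- vapply(lags, function(l) {
    n <- length(t)
    cor(sig$v[1:(n - l)], dsig$v[(1 + l):n])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 15)

  # jittered delays: recovered per-sample delay stays within [0, bound]
  tl <- seq(0.0001, 10, by = 0.0001)
  big <- data.frame(t_s = tl, v = tl)
  j <- apply_latency(big, latency_model("jittered", 0.015), seed = 4)
  d <- tl - j$v
  expect_gte(min(d), -1e-12)
  expect_lte(max(d), 0.015 + 1e-12)
  expect_true(all(diff(j$v) >= -1e-12))  # order-preserving
  expect_identical(j, apply_latency(big, latency_model("jittered", 0.015),
                                    seed = 4))
})

test_that("a uniform phantom gives a settled force, steady rate, no presses", {
  ph <- generate_phantom(phantom_config(replicas = 0L), seed = 1)
  cal <- cached_cal()
  cfg <- session_config(duration = 20, seed = 2)
  log <- run_session(ph, subject_model(), control_config(),
                     izhikevich_params(), cal, cfg,
                     make_trajectory("raster", list(speed = 15)))
  late <- log$force$fz_N[log$force$t_s > 1]
  expect_lt(max(abs(late - cfg$force_setpoint)), 1e-3)
  # near-constant spike rate over 2 s bins after settle
  bins <- cut(log$spikes$times[log$spikes$times > 2], seq(2, 20, by = 2))
  rates <- as.numeric(table(bins)) / 2
  expect_lt(max(rates) - min(rates), 3)
  expect_equal(nrow(log$responses), 0L)
  expect_lte(max(log$force$fz_N), 0.5)
})

test_that("crossing a stiff inclusion raises the spike rate transiently", {
  ph <- single_inclusion_phantom(center = c(50, 50))
  cal <- cached_cal()
  traj <- make_trajectory("waypoints",
                          list(points = rbind(c(10, 50), c(90, 50)),
                               speed = 10))
  log <- run_session(ph, NULL, control_config(), izhikevich_params(), cal,
                     session_config(duration = 12, seed = 1), traj)
  # when does the stage enter the footprint?
  inside <- abs(log$stage$x_mm - 50) <= 5 & abs(log$stage$y_mm - 50) <= 5
  t_in <- range(log$stage$t_s[inside])
  rate_in <- sum(log$spikes$times >= t_in[1] &
                 log$spikes$times <= t_in[1] + 0.3) / 0.3
  base_win <- c(t_in[1] - 1.5, t_in[1] - 0.5)
  rate_base <- sum(log$spikes$times >= base_win[1] &
                   log$spikes$times <= base_win[2]) / 1
  expect_gt(rate_in, rate_base + 10)
  expect_lte(max(log$force$fz_N), 0.5)
})

test_that("sessions are reproducible and modes differ only via latency", {
  ph <- generate_phantom(phantom_config(), seed = 4)
  cal <- cached_cal()
  run_once <- function(mode, latency = NULL, seed = 9) {
    run_session(ph, subject_model(), control_config(), izhikevich_params(),
                cal, session_config(duration = 15, mode = mode,
                                    latency = latency, seed = seed),
                make_trajectory("raster", list(speed = 15)))
  }
  l1 <- run_once("ILS")
  l2 <- run_once("ILS")
  d1 <- tempfile(); d2 <- tempfile()
  write_session_log(l1, d1)
  write_session_log(l2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = paste("bytes of", f))
  }
  # with a zero latency bound, ILS and NILS collapse to the same log
  z <- latency_model("fixed", 0)
  ils <- run_once("ILS", latency = z)
  nils <- run_once("NILS", latency = z)
  expect_identical(ils$spikes, nils$spikes)
  expect_identical(ils$responses, nils$responses)
})

test_that("session log directories round-trip", {
  ph <- generate_phantom(phantom_config(), seed = 4)
  cal <- cached_cal()
  log <- run_session(ph, subject_model(), control_config(),
                     izhikevich_params(), cal,
                     session_config(duration = 10, seed = 1),
                     make_trajectory("raster", list(speed = 20)))
  d <- tempfile()
  write_session_log(log, d)
  back <- read_session_log(d)
  expect_equal(back$stage$x_mm, log$stage$x_mm, tolerance = 1e-12)
  expect_equal(back$spikes$times, log$spikes$times, tolerance = 1e-12)
  expect_equal(back$config$session$force_setpoint,
               log$config$session$force_setpoint)
})

test_that("raster pitch covers every inclusion and waypoint edge cases hold", {
  ph <- generate_phantom(phantom_config(), seed = 8)
  cal <- cached_cal()
  ctl <- control_config()
  log <- run_session(ph, NULL, ctl, izhikevich_params(), cal,
                     session_config(duration = 90, seed = 1),
                     make_trajectory("raster", list(pitch = 10, speed = 18,
                                                    x_range = c(5, 95),
                                                    y_range = c(5, 95)),
                                     control_cfg = ctl))
  for (i in seq_len(nrow(ph$inclusions))) {
    dmin <- min(sqrt((log$stage$x_mm - ph$inclusions$x[i])^2 +
                     (log$stage$y_mm - ph$inclusions$y[i])^2))
    expect_lt(dmin, 5.5)
  }
  # no waypoints: the hand rests inside the dead zone, the stage holds still
  still <- make_trajectory("waypoints", list(points = NULL))
  expect_equal(still(1, c(50, 50)), c(0, 0, 0))
  expect_error(make_trajectory("waypoints",
                               list(points = rbind(c(150, 50)))),
               "workspace")
})

test_that("replaying a recorded hand log reproduces the stage path", {
  ph <- generate_phantom(phantom_config(), seed = 4)
  cal <- cached_cal()
  cfg <- session_config(duration = 10, seed = 5)
  orig <- run_session(ph, NULL, control_config(), izhikevich_params(), cal,
                      cfg, make_trajectory("raster", list(speed = 15)))
  replay <- run_session(ph, NULL, control_config(), izhikevich_params(), cal,
                        cfg, make_trajectory("replay",
                                             list(hand = orig$hand)))
  expect_lt(max(abs(replay$stage$x_mm - orig$stage$x_mm)), 0.5)
  expect_lt(max(abs(replay$stage$y_mm - orig$stage$y_mm)), 0.5)
})

test_that("configuration mismatches abort before simulation", {
  ph <- generate_phantom(phantom_config(), seed = 1)
  cal <- cached_cal()
  expect_error(
    run_session(ph, NULL, control_config(workspace = c(0, 150, 0, 100)),
                izhikevich_params(), cal, session_config(duration = 5)),
    "footprint")
  expect_error(
    run_session(ph, NULL, control_config(), izhikevich_params(dt = 0.1),
                cal, session_config(duration = 5)),
    "encoder_rate")
  expect_error(session_config(force_setpoint = 0.6), "<= 0.5")
})
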