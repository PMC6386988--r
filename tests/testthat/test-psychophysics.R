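make_responses <- function(xy) {
  data.frame(t_s = seq_len(nrow(xy)), x_mm = xy[, 1], y_mm = xy[, 2])
}

test_that("responses classify by distance to the nearest inclusion centre", {
  ph <- single_inclusion_phantom(center = c(50, 50))
  at_centre <- make_responses(cbind(50, 50))
  for (tol in c(5, 10, 15, 20))
    expect_equal(classify_responses(at_centre, ph, tol)$tp_count, 1L)
  # 12 mm away is an FP at the 10 mm tolerance
  cls <- classify_responses(make_responses(cbind(62, 50)), ph, 10)
  expect_equal(cls$fp_count, 1L)
  # exactly at the tolerance counts as TP
  cls <- classify_responses(make_responses(cbind(60, 50)), ph, 10)
  expect_equal(cls$tp_count, 1L)
  expect_equal(cls$detail$distance_mm, 10)
  # empty phantom: every press is an FP, not an error
  ph0 <- generate_phantom(phantom_config(replicas = 0L), seed = 1)
  cls0 <- classify_responses(make_responses(cbind(c(10, 20), c(10, 20))),
                             ph0, 10)
  expect_equal(cls0$fp_count, 2L)
})

test_that("accuracy definitions behave as documented", {
  ph <- single_inclusion_phantom(center = c(50, 50))
  all_tp <- classify_responses(make_responses(cbind(c(50, 51), c(50, 50))),
                               ph, 10)
  expect_equal(accuracy(all_tp), 1)
  half <- classify_responses(make_responses(cbind(c(50, 90), c(50, 90))),
                             ph, 10)
  expect_equal(accuracy(half), 0.5)
  expect_equal(accuracy(half, "positives"), 1)  # TP / (responses - FP) = TP/TP
  none <- classify_responses(make_responses(matrix(numeric(0), ncol = 2)),
                             ph, 10)
  expect_error(accuracy(none), "zero responses")
})

test_that("TP counts are monotone in tolerance and counts always partition", {
  ph <- generate_phantom(phantom_config(), seed = 5)
  set.seed(123)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    resp <- make_responses(cbind(runif(n, 0, 100), runif(n, 0, 100)))
    tps <- vapply(c(5, 10, 15, 20), function(tol) {
      cls <- classify_responses(resp, ph, tol)
      expect_equal(cls$tp_count + cls$fp_count, n)
      cls$tp_count
    }, numeric(1))
    expect_true(all(diff(tps) >= 0))
  }
})

test_that("tolerance sweep averages sessions and shows scatter sensitivity", {
  ph <- generate_phantom(phantom_config(), seed = 5)
  centres <- make_responses(as.matrix(ph$inclusions[c("x", "y")]))
  curve <- tolerance_sweep(centres, ph)
  expect_equal(curve$mean_tp, rep(12, 4))
  expect_equal(curve$mean_accuracy, rep(1, 4))
  # scattered presses: wide tolerance recovers presses that the tight loses
  set.seed(9)
  sessions <- lapply(1:4, function(i) {
    xy <- as.matrix(ph$inclusions[c("x", "y")]) +
      matrix(rnorm(24, sd = 4), ncol = 2)
    make_responses(pmin(pmax(xy, 0), 100))
  })
  curve <- tolerance_sweep(sessions, ph)
  expect_gt(curve$mean_tp[curve$tolerance_mm == 20],
            curve$mean_tp[curve$tolerance_mm == 5])
  expect_true(all(diff(curve$mean_tp) >= 0))
})

test_that("identification rates count inclusions once and by material", {
  ph <- generate_phantom(phantom_config(), seed = 5)
  centres <- make_responses(as.matrix(ph$inclusions[c("x", "y")]))
  rates <- identification_rate_by_material(centres, ph)
  expect_equal(rates$mean_rate, rep(1, 4))
  expect_equal(rates$material,
               c("DS20", "DS30", "PDMS", "SC"))  # increasing stiffness
  none <- make_responses(matrix(numeric(0), ncol = 2))
  rates0 <- identification_rate_by_material(none, ph)
  expect_equal(rates0$mean_rate, rep(0, 4))
  # repeated presses on one inclusion still count it once
  rep3 <- make_responses(cbind(rep(ph$inclusions$x[1], 3),
                               rep(ph$inclusions$y[1], 3)))
  r <- identification_rate_by_material(rep3, ph)
  expect_equal(sum(r$mean_rate * 3), 1)  # exactly one inclusion identified
  expect_error(identification_rate_by_material(centres, ph,
                                               materials = "Steel"),
               "absent")
})

test_that("a subject sensitive only above 3 N/mm yields stiff > soft rates", {
  ph <- generate_phantom(phantom_config(), seed = 6)
  sessions <- lapply(1:6, function(s) {
    detected <- psychometric_response(ph$inclusions$stiffness_k,
                                      a_thr = 3.2, b_scale = 0.1, seed = s)
    hit <- ph$inclusions[detected, ]
    make_responses(cbind(hit$x, hit$y))
  })
  rates <- identification_rate_by_material(sessions, ph)
  soft <- mean(rates$mean_rate[rates$material %in% c("DS20", "DS30")])
  stiff <- mean(rates$mean_rate[rates$material %in% c("PDMS", "SC")])
  expect_gt(stiff, soft)
})

test_that("logistic CDF fit recovers exact parameters to solver tolerance", {
  x <- c(2.74, 2.88, 3.68, 3.69)
  r <- 1 / (1 + exp(-(x - 3.0) / 0.3))
  fit <- fit_cdf(x, r)
  expect_true(fit$converged)
  expect_lt(abs(fit$a_thr - 3.0) / 3.0, 1e-6)
  expect_lt(abs(fit$b_scale - 0.3) / 0.3, 1e-6)
  # midpoint identity of the fitted curve
  expect_equal(1 / (1 + exp(-(fit$a_thr - fit$a_thr) / fit$b_scale)), 0.5)
  # brute-force grid search confirms the least-squares minimum
  g <- grid_fit_cdf(x, r, seq(2.8, 3.2, by = 0.01), seq(0.1, 0.5, by = 0.01))
  expect_equal(unname(g["a"]), 3.0, tolerance = 1e-9)
  expect_equal(unname(g["b"]), 0.3, tolerance = 1e-9)
  expect_gte(g["rss"], fit$rss - 1e-12)
})

test_that("fit flags degenerate and unidentifiable inputs", {
  expect_error(fit_cdf(c(3, 3), c(0.2, 0.8)), "distinct")
  expect_error(fit_cdf(c(2, 3), c(0.2, 1.4)), "\\[0, 1\\]")
  flat <- fit_cdf(c(2.74, 2.88, 3.68), rep(0.5, 3))
  expect_false(flat$converged)
  expect_match(flat$reason, "unidentifiable")
})

test_that("threshold estimation bias shrinks with trials per level", {
  x <- c(2.74, 2.88, 3.68, 3.69)
  p <- 1 / (1 + exp(-(x - 3.0) / 0.3))
  mean_abs_bias <- function(n_per, reps) {
    a_hat <- vapply(seq_len(reps), function(rep) {
      set.seed(1000 * n_per + rep)
      rates <- rbinom(length(x), n_per, p) / n_per
      fit_cdf(x, rates)$a_thr
    }, numeric(1))
    mean(abs(a_hat - 3.0), na.rm = TRUE)
  }
  b50 <- mean_abs_bias(50, 40)
  b1000 <- mean_abs_bias(1000, 40)
  expect_lt(b1000, b50)
})

test_that("session analysis bundles and serialises the full report", {
  ph <- generate_phantom(phantom_config(), seed = 5)
  centres <- make_responses(as.matrix(ph$inclusions[c("x", "y")]))
  f <- tempfile(fileext = ".json")
  an <- analyze_sessions(centres, ph, file = f)
  expect_named(an, c("tolerance_curve", "material_rates", "fit"))
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$tolerance_curve$mean_tp, rep(12, 4))
})
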