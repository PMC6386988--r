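test_that("default phantom layout respects counts, margins and non-overlap", {
  ph <- generate_phantom(phantom_config(), seed = 7)
  inc <- ph$inclusions
  expect_equal(nrow(inc), 12L)
  expect_equal(as.integer(table(inc$material)), rep(3L, 4))
  # inside the footprint with the configured edge clearance
  expect_true(all(inc$x >= 10 & inc$x <= 90 & inc$y >= 10 & inc$y <= 90))
  d <- as.matrix(dist(inc[c("x", "y")]))
  diag(d) <- Inf
  expect_gt(min(d), 2 * inc$radius[1])
})

test_that("phantom generation is a pure function of config and seed", {
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_phantom(generate_phantom(phantom_config(), seed = 11), f1)
  write_phantom(generate_phantom(phantom_config(), seed = 11), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed moves the layout
  ph3 <- generate_phantom(phantom_config(), seed = 12)
  ph1 <- read_phantom(f1)
  expect_false(isTRUE(all.equal(ph1$inclusions$x, ph3$inclusions$x)))
})

test_that("degenerate and infeasible layouts are handled explicitly", {
  ph0 <- generate_phantom(phantom_config(replicas = 0L), seed = 1)
  expect_equal(nrow(ph0$inclusions), 0L)
  expect_error(
    generate_phantom(phantom_config(radius = 20, max_attempts = 50), seed = 1),
    "inclusion"
  )
})

test_that("local stiffness field matches the material table and tie-breaks", {
  ph <- generate_phantom(phantom_config(), seed = 3)
  sc <- ph$inclusions[ph$inclusions$material == "SC", ][1, ]
  expect_equal(local_stiffness(ph, c(sc$x, sc$y)), 3.69)
  # boundary belongs to the inclusion when blend_width = 0
  expect_equal(local_stiffness(ph, c(sc$x + sc$radius, sc$y)), 3.69)
  # a point far from every inclusion reads the matrix stiffness
  grid <- expand.grid(x = seq(5, 95, by = 2), y = seq(5, 95, by = 2))
  dmin <- apply(grid, 1, function(p)
    min(sqrt((ph$inclusions$x - p[1])^2 + (ph$inclusions$y - p[2])^2)))
  far <- grid[which.max(dmin), ]
  expect_equal(local_stiffness(ph, as.numeric(far)), 2.14)
  expect_error(local_stiffness(ph, c(-1, 50)), "outside")
})

test_that("blend band interpolates linearly and keeps the field continuous", {
  ph <- single_inclusion_phantom()
  ph$blend_width <- 2
  r <- ph$inclusions$radius[1]
  k_in <- ph$inclusions$stiffness_k[1]
  mid <- local_stiffness(ph, c(50 + r + 1, 50))
  expect_equal(mid, (k_in + ph$matrix_k) / 2)
  xs <- seq(50, 60, by = 0.05)
  ks <- local_stiffness(ph, cbind(xs, 50))
  expect_lt(max(abs(diff(ks))), 0.05 * (k_in - ph$matrix_k))
})

test_that("contact force is the linear law with monotone behaviour", {
  expect_equal(contact_force(2.14, 0), 0)
  expect_equal(contact_force(2.14, 0.2), 0.428)
  expect_error(contact_force(2.14, -0.1), ">= 0")
  depths <- seq(0, 0.3, by = 0.05)
  expect_true(all(diff(contact_force(3.69, depths)) > 0))
  expect_true(all(contact_force(3.69, depths) >= contact_force(2.14, depths)))
})

test_that("indentation stops at the force threshold and is reproducible", {
  ph <- generate_phantom(phantom_config(replicas = 0L), seed = 1)
  s <- simulate_indentation(ph, c(50, 50))  # matrix k = 2.14
  k <- 2.14
  dz <- 0.125 / 100
  expect_gte(tail(s$force_N, 1), 0.5)
  expect_lt(tail(s$force_N, 1), 0.5 + k * dz)
  expect_equal(tail(s$depth_mm, 1), 0.5 / k, tolerance = dz / (0.5 / k))
  expect_true(all(diff(s$depth_mm) > 0))
  s2 <- simulate_indentation(ph, c(50, 50))
  expect_identical(s, s2)
  sn1 <- simulate_indentation(ph, c(50, 50), noise_sd = 0.01, seed = 5)
  sn2 <- simulate_indentation(ph, c(50, 50), noise_sd = 0.01, seed = 5)
  expect_identical(sn1, sn2)
})

test_that("stiffness characterization matches the least-squares oracle", {
  z <- seq(0.01, 0.15, by = 0.01)
  exact <- data.frame(depth_mm = z, force_N = 3.68 * z)
  est <- characterize_stiffness(exact)
  expect_equal(unname(est$per_series), 3.68, tolerance = 1e-12)

  ph <- single_inclusion_phantom()
  trials <- lapply(1:5, function(i)
    simulate_indentation(ph, c(50, 50), noise_sd = 0.01, seed = i))
  pooled <- characterize_stiffness(trials)
  oracle <- sapply(trials, function(s) ls_slope(s$depth_mm, s$force_N))
  expect_equal(unname(pooled$per_series), oracle, tolerance = 1e-12)
  expect_equal(pooled$summary$median, 3.69, tolerance = 0.01)
  expect_equal(pooled$summary$n, 5L)

  expect_error(characterize_stiffness(exact[1, , drop = FALSE]), ">= 2")
})

test_that("phantom JSON and indentation CSV round-trip losslessly", {
  ph <- generate_phantom(phantom_config(), seed = 9)
  f <- tempfile(fileext = ".json")
  write_phantom(ph, f)
  ph2 <- read_phantom(f)
  expect_equal(ph2$inclusions, ph$inclusions)
  expect_equal(ph2$matrix_k, ph$matrix_k)
  f2 <- tempfile(fileext = ".json")
  write_phantom(ph2, f2)
  expect_identical(readLines(f), readLines(f2))

  s <- simulate_indentation(ph, c(50, 50))
  fc <- tempfile(fileext = ".csv")
  write_indentation(s, fc)
  s2 <- read_indentation(fc)
  expect_equal(s2$depth_mm, s$depth_mm)
  expect_equal(s2$force_N, s$force_N, tolerance = 1e-12)
})
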