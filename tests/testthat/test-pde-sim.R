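p0 <- default_params()

test_that("initial conditions reproduce the seeded colony", {
  cfg <- sim_config(dx = 2^-10)
  ic <- initial_condition_1d(cfg)
  expect_equal(ic$M[1], cfg$h * (1 - (cfg$dx / 2)^4 / cfg$d^4), tolerance = 1e-12)
  expect_equal(ic$M[1], 0.1, tolerance = 1e-4)
  expect_true(all(ic$M[ic$x > cfg$d] == 0))
  expect_true(all(ic$S == 1))
  expect_error(sim_config(d = 2, H = 1))

  cfg2 <- sim_config(H = 1, L = 1, dx = 2^-8, dy = 2^-5)
  ic2 <- initial_condition_2d(cfg2)
  # first and middle y rows sit at the cosine extremes of the 1D profile
  prof1 <- ifelse(ic2$x <= cfg2$d, cfg2$h * (1 - ic2$x^4 / cfg2$d^4), 0)
  jmid <- which.min(abs(ic2$y - cfg2$L / 2))
  expect_equal(ic2$M[, 1], prof1 * (1 + cos(2 * pi * ic2$y[1]) / 5),
               tolerance = 1e-12)
  expect_equal(ic2$M[, jmid], prof1 * (1 + cos(2 * pi * ic2$y[jmid]) / 5),
               tolerance = 1e-12)
  # the transverse mean recovers the 1D profile (cosine integrates to zero)
  expect_equal(rowMeans(ic2$M), prof1, tolerance = 1e-12)
  expect_lt(max(ic2$M), 0.12 + 1e-12)
})

test_that("conservative flux form preserves total biomass with reactions off", {
  cfg <- sim_config(dx = 2^-8, t_end = 2, snapshot_times = c(0, 2))
  ic <- initial_condition_1d(cfg)
  snaps <- simulate_pde(cfg, p0, ic, reactions = FALSE)
  m0 <- sum(snaps[[1]]$M)
  m1 <- sum(snaps[[2]]$M)
  expect_lt(abs(m1 - m0) / m0, 1e-12)
  expect_true(all(snaps[[2]]$S == 1))
})

test_that("uniform fields see no diffusive flux, only reactions", {
  cfg <- sim_config(dx = 2^-6, dt = 1e-3)
  st <- structure(list(t = 0, M = rep(0.3, 64), S = rep(1, 64),
                       x = seq(2^-7, 1 - 2^-7, by = 2^-6), dx = 2^-6,
                       y = NULL, dy = NULL, nx = 64L, ny = NULL),
                  class = "field_state")
  out <- step_trapezoidal(st, cfg, p0)
  expect_lt(diff(range(out$M)), 1e-13)     # stays spatially uniform
  expect_lt(diff(range(out$S)), 1e-13)
  expect_gt(out$M[1], 0.3)                 # f(1) > lambda: net growth
  expect_lt(out$S[1], 1)                   # substrate consumed
})

test_that("substrate decreases monotonically and fields stay in bounds", {
  cfg <- sim_config(dx = 2^-9, t_end = 10, snapshot_times = seq(0, 10, by = 2))
  snaps <- simulate_pde(cfg, p0)
  S_prev <- snaps[[1]]$S
  for (k in 2:length(snaps)) {
    expect_true(all(snaps[[k]]$S <= S_prev + 1e-12))
    S_prev <- snaps[[k]]$S
    expect_true(all(snaps[[k]]$M > -1e-10))
    expect_true(all(snaps[[k]]$M < 1 - 1e-6))
    expect_true(all(snaps[[k]]$S >= 0))
  }
})

test_that("a transversely symmetric 2D state stays symmetric", {
  cfg <- sim_config(H = 0.5, L = 0.25, dx = 2^-6, dy = 2^-6, dt = 1e-3,
                    d = 5 / 127, h = 0.1)
  ic <- initial_condition_2d(cfg)
  st <- ic
  for (k in 1:5) st <- step_trapezoidal(st, cfg, p0)
  # the cosine mode is even about y = L/2: mirror symmetry in the y index
  expect_equal(st$M, st$M[, rev(seq_len(st$ny))], tolerance = 1e-10)
  expect_gt(max(abs(st$M - ic$M)), 0)      # and something actually evolved
})

test_that("wave-speed fit recovers an exactly linear interface", {
  dx <- 0.01
  x <- seq(dx / 2, 2 - dx / 2, by = dx)
  mk <- function(t) {
    pos <- 0.25 + 0.02 * t
    structure(list(t = t, M = ifelse(x <= pos, 0.5, 0), S = rep(1, length(x)),
                   x = x, dx = dx, y = NULL, dy = NULL,
                   nx = length(x), ny = NULL),
              class = "field_state")
  }
  snaps <- structure(lapply(seq(0, 30, by = 1) * 2.5, mk),
                     class = c("sim_snapshots", "list"))
  cfg <- sim_config(H = 2, dx = dx, t_end = 75)
  fit <- estimate_wave_speed(snaps, cfg)
  expect_equal(fit$slope, 0.02, tolerance = 1e-10)
  expect_lt(fit$rms_residual, 1e-10)
})

test_that("L1 profile distance has the metric trivialities", {
  cfg <- sim_config(dx = 2^-8, t_end = 4, snapshot_times = c(0, 2, 4))
  snaps <- simulate_pde(cfg, p0)
  l1 <- l1_profile_difference(snaps)
  expect_equal(l1$l1[3], 0)
  expect_true(all(l1$l1[1:2] > 0))
  doubled <- snaps
  doubled[[1]]$M <- 2 * snaps[[1]]$M
  zero <- snaps[[1]]; zero$M <- 0 * zero$M
  base <- sum(abs(snaps[[1]]$M)) * cfg$dx
  l1z <- l1_profile_difference(structure(list(zero, doubled[[1]]),
                                         class = c("sim_snapshots", "list")),
                               ref_index = 1)
  expect_equal(l1z$l1[2], 2 * base, tolerance = 1e-12)
})

test_that("developed coarse-grid profiles translate at the fitted speed", {
  cfg <- sim_config(dx = 2^-10, t_end = 40, snapshot_times = seq(0, 40, by = 2))
  snaps <- simulate_pde(cfg, p0)
  fit <- estimate_wave_speed(snaps, cfg)
  n <- length(snaps)
  a <- snaps[[n - 2]]; b <- snaps[[n]]
  shift <- fit$slope * (b$t - a$t)
  Mshift <- stats::approx(a$x + shift, a$M, b$x, yleft = NA, yright = 0)$y
  ok <- !is.na(Mshift)
  l1 <- sum(abs(b$M[ok] - Mshift[ok])) * cfg$dx
  expect_lt(l1 / (sum(a$M) * cfg$dx), 0.02)
})

test_that("embedded wave with zero amplitude reproduces the 1D profile", {
  res <- default_tw()
  cfg <- sim_config(H = 1, L = 0.5, dx = 2^-8, dy = 2^-5)
  st <- perturbed_tw_initial_condition(res$profile, n = 1, amplitude = 0, cfg)
  expect_equal(diff(range(st$M[10, ])), 0)           # no transverse variation
  expect_true(all(st$M[st$x > 0.75, 1] == 0))        # front at 0.75 H
  st2 <- perturbed_tw_initial_condition(res$profile, n = 1, amplitude = 0.05, cfg)
  # transverse mean of the perturbation vanishes for n >= 1
  expect_equal(rowMeans(st2$M), st$M[, 1], tolerance = 1e-12)
  expect_gt(transverse_mode_amplitude(st2, 1), 0.04)
  expect_error(perturbed_tw_initial_condition(res$profile, 1, 0.9, cfg),
               "amplitude")
})
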