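pc <- continuation_params()

test_that("launch point sits on the rising nullcline branch", {
  lp <- launch_point(1e-3, pc)
  expect_equal(nullcline_ell(lp[["S"]], pc), 1e-3, tolerance = 1e-12)
  expect_lt(lp[["S"]], f_inverse(pc$lam, pc))
  # shrinking the offset moves the launch towards the rest state
  sm <- as.numeric(solve_s_minus_infinity(pc))
  s6 <- launch_point(1e-6, pc)[["S"]]
  expect_gt(s6, sm)
  expect_lt(s6 - sm, launch_point(1e-3, pc)[["S"]] - sm)
  expect_lt(s6 - sm, 1e-4)
  # no root above the nullcline maximum
  expect_error(launch_point(10, pc), "nullcline maximum")
})

test_that("shooting residual degenerates to the launch mismatch as T -> 0", {
  cfg <- continuation_config()
  r <- shooting_residual(0.2, 1e-12, 0.3, pc, cfg)
  lp <- launch_point(cfg$eps0, pc)
  expect_equal(as.numeric(r), c(cfg$eps0 - cfg$eps1, lp[["S"]] - 1),
               tolerance = 1e-6)
})

test_that("terminal substrate level changes sign across the connecting speed", {
  cfg <- continuation_config()
  Tfix <- 6e5
  r_lo <- shooting_residual(0.18, Tfix, 0.3, pc, cfg)
  r_hi <- shooting_residual(0.25, Tfix, 0.3, pc, cfg)
  expect_true(sign(r_lo[2]) != sign(r_hi[2]) || r_hi[2] == 0)
})

test_that("connection speed agrees with the wave-speed bisection", {
  rb <- suppressWarnings(find_wave_speed(pc))
  pt <- solve_connection(0.3, pc, continuation_config(), guess = c(0.15, NA))
  expect_true(pt$converged)
  expect_lt(pt$residual_norm, 1e-2)
  expect_lt(abs(pt$v - rb$v) / rb$v, 0.01)
  expect_gt(pt$T, 0)
  # the converged orbit lands on the (eps1, 1) endpoint ball
  nM <- length(pt$orbit$M)
  expect_lt(abs(pt$orbit$S[nM] - 1), 5e-3)
})

test_that("gamma sweep is monotone and stops at the non-existence side", {
  cfg <- continuation_config(gamma_grid = c(0.3, 0.25, 0.2, 0.07),
                             init_v = 0.2)
  sw <- sweep_gamma(pc, cfg)
  expect_length(sw, 3)                               # 0.07 fails
  vs <- vapply(sw, function(q) q$v, numeric(1))
  expect_true(all(diff(vs) > 0))                     # v grows as gamma falls
  expect_true(all(vapply(sw, function(q) q$converged, logical(1))))
  # the failure boundary brackets the G-positivity threshold (~0.109)
  thr_lo <- attr(sw, "failure_gamma")
  expect_equal(thr_lo, 0.07)
  expect_lt(thr_lo, 0.109)
  expect_gt(sw[[3]]$gamma, 0.109)
})
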