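p0 <- default_params()

test_that("scaled vector field vanishes at the rest states and points the right way", {
  expect_equal(scaled_vector_field(0, 1, 0.01, p0), c(0, 0))
  sm <- as.numeric(solve_s_minus_infinity(model_params(kappa = 1, lam = 0.3)))
  fld <- scaled_vector_field(0, sm, 0.01, model_params(kappa = 1, lam = 0.3))
  expect_equal(fld[1], 0, tolerance = 1e-9)   # ell(s_-inf) = 0
  expect_equal(fld[2], 0)
  # substrate strictly decreases along the negated field wherever m > 0
  for (m in c(0.1, 0.5, 0.9)) {
    for (s in c(0.05, 0.5, 0.99)) {
      expect_lt(scaled_vector_field(m, s, 0.01, p0)[2], 0)
    }
  }
  expect_error(scaled_vector_field(0.5, 0.5, -1, p0))
})

test_that("orbit exit classes split below and above the wave speed", {
  cfg <- solver_config()
  fast <- integrate_orbit(0.1, p0, cfg, store = FALSE)
  expect_identical(fast$exit, "substrate_line")
  slow <- integrate_orbit(0.001, p0, cfg, store = FALSE)
  expect_identical(slow$exit, "biomass_axis")
  expect_lt(fast$max_M, 1)
  expect_lt(slow$max_M, 1)
})

test_that("bisection converges with shrinking brackets, independent of the guess", {
  res <- default_tw()
  widths <- res$bracket_history[, 2] - res$bracket_history[, 1]
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[length(widths)], 1e-4 * res$v * 2)
  expect_equal(res$v, 0.01454, tolerance = 5e-3)

  res2 <- find_wave_speed(p0, solver_config(v_init = 0.0008))
  expect_equal(res2$v, res$v, tolerance = 2 * 1e-4)
})

test_that("bisection speed is stable under integrator refinement", {
  res <- default_tw()
  fine <- find_wave_speed(p0, solver_config(step_cap = 5e-4, rel_tol = 1e-9))
  expect_lt(abs(fine$v - res$v) / res$v, 1e-3)
})

test_that("reconstructed profile satisfies the wave's integral identities", {
  res <- default_tw()
  pr <- res$profile
  expect_equal(max(pr$xi), 0)
  expect_equal(pr$S[length(pr$S)], 1, tolerance = 2e-3)  # S(0) = 1 - O(eps)
  expect_true(all(diff(pr$xi) >= 0))
  expect_true(all(diff(pr$S) >= -1e-12))

  # accumulated biomass: closed form against direct quadrature of M dxi
  direct <- trapz(pr$xi, pr$M)
  expect_lt(abs(direct - (max(pr$omega) - min(pr$omega))) / direct, 0.01)
  # mass balance: omega_inf = v (1 - s_-inf) / (lambda gamma)
  expect_equal(pr$omega_inf, res$v / (p0$lam * p0$gamma), tolerance = 1e-10)
  expect_lt(abs(direct - pr$omega_inf) / pr$omega_inf, 0.01)

  # biomass peaks where the orbit crosses the nullcline (the interior sign
  # change of dM; the stored orbit, marginally on the fast side of the
  # bisection, re-grows slightly at the depleted rear)
  orb <- res$orbit
  dM <- diff(orb$M)
  icr <- which(dM[-length(dM)] > 0 & dM[-1] <= 0)[1] + 1L
  expect_lt(abs(orb$M[icr] - nullcline_ell(orb$S[icr], p0)), 0.01)
  expect_lt(abs(max(pr$M) - orb$M[icr]), 0.01)
})

test_that("orbits are ordered in the wave speed", {
  cfg <- solver_config()
  vs <- c(0.01, 0.0145, 0.02)
  orbs <- lapply(vs, integrate_orbit, p = p0, cfg = cfg, store = TRUE)
  sgrid <- seq(0.2, 0.9, by = 0.05)
  maps <- lapply(orbs, function(o) stats::approx(rev(o$S), rev(o$M), sgrid, ties = "ordered")$y)
  expect_true(all(maps[[1]] <= maps[[2]] + 1e-8))
  expect_true(all(maps[[2]] <= maps[[3]] + 1e-8))
})

test_that("flux vanishes and particle speed approaches v at the sharp front", {
  res <- default_tw()
  pr <- res$profile
  n <- length(pr$xi)
  ipk <- which.max(pr$M)
  sel <- seq(ipk, n)                       # front side, M decreasing to 0
  idx <- sel[pr$M[sel] > 5e-3 & pr$M[sel] < 2e-2]
  dMdxi <- diff(pr$M[idx]) / diff(pr$xi[idx])
  mmid <- 0.5 * (pr$M[idx][-1] + pr$M[idx][-length(idx)])
  Dmid <- diffusion_D(mmid, p0)
  flux <- Dmid * dMdxi
  particle <- (Dmid / mmid) * dMdxi
  peak_flux <- max(abs(diffusion_D(pr$M, p0) * c(0, diff(pr$M) / diff(pr$xi))),
                   na.rm = TRUE)
  expect_lt(max(abs(flux)) / peak_flux, 0.05)
  expect_lt(max(abs(particle + res$v) / res$v), 0.05)
})

test_that("front regularity exponent is the diffusion-exponent reciprocal", {
  res <- default_tw()
  fit <- front_exponent_fit(res$profile, p0)
  expect_equal(fit$exponent, 0.25, tolerance = 0.02 / 0.25)

  p2 <- model_params(a = 2, b = 2)
  res2 <- find_wave_speed(p2)
  fit2 <- front_exponent_fit(res2$profile, p2)
  expect_lt(abs(fit2$exponent - 0.5), 0.03)
})

test_that("lower-bound envelope brackets the orbit near the front", {
  res <- default_tw()
  v <- res$v
  expect_equal(as.numeric(lower_bound_profile(1, v, p0)), 0)
  sg <- seq(0.95, 0.999, by = 0.004)
  mb <- as.numeric(lower_bound_profile(sg, v, p0))
  expect_true(all(diff(mb) < 0))           # decreasing towards s = 1
  orb <- res$orbit
  Morb <- stats::approx(rev(orb$S), rev(orb$M), sg, ties = "ordered")$y
  ell <- nullcline_ell(sg, p0)
  expect_true(all(ell < mb))
  expect_true(all(mb < Morb))
})

test_that("wave speed decreases with the cell-loss rate", {
  vs <- vapply(c(0.38, 0.42, 0.6), function(l) {
    suppressWarnings(find_wave_speed(model_params(lam = l))$v)
  }, numeric(1))
  expect_true(all(diff(vs) < 0))
})

test_that("the search reports failure in the non-existence regime", {
  png <- model_params(kappa = 1, lam = 0.3, a = 2, b = 2, gamma = 0.05)
  expect_false(existence_report(png)$cond_G_positive)
  cfg <- solver_config(v_init = 0.001, v_min = 1e-8, v_max = 1)
  expect_error(suppressWarnings(find_wave_speed(png, cfg)),
               "no travelling wave found")
})
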