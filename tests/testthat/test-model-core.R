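p0 <- model_params()

test_that("closed-form model functions match direct evaluation", {
  expect_equal(diffusion_D(0, p0), 0)
  expect_equal(diffusion_D(0.5, p0), 1e-6)            # a = b makes the ratio 1
  expect_equal(diffusion_D(0.9, p0), 1e-6 * 0.9^4 / 0.1^4, tolerance = 1e-12)
  expect_true(all(diff(diffusion_D(seq(0, 0.99, by = 0.01), p0)) > 0))

  expect_equal(reaction_f(0, p0), 0)
  expect_equal(reaction_f(p0$kappa, p0), 0.5)
  expect_equal(reaction_f(1, p0), 100 / 101, tolerance = 1e-12)

  expect_equal(f_inverse(0.5, p0), p0$kappa)
  expect_equal(f_inverse(0.42, p0), 0.01 * 0.42 / 0.58, tolerance = 1e-12)
  y <- seq(0.1, 0.9, by = 0.1)
  expect_equal(reaction_f(f_inverse(y, p0), p0), y, tolerance = 1e-14)

  expect_equal(integral_F(1, p0), 0)
  p1 <- model_params(kappa = 1, lam = 0.3)
  F1319 <- integral_F(0.1319, p1)
  expect_equal(F1319, 1 - 0.1319 - log(0.1319), tolerance = 1e-14)
  expect_lt(abs(0.1319 + 0.3 * F1319 - 1), 2e-4)      # consistency with the root

  expect_equal(nullcline_ell(1, p0), 0)
  expect_equal(curly_G(1, p0), 0)
})

test_that("domain violations are rejected", {
  expect_error(diffusion_D(-0.1, p0))
  expect_error(diffusion_D(1, p0))
  expect_error(reaction_f(-1, p0))
  expect_error(f_inverse(1, p0))
  expect_error(integral_F(0, p0))
  expect_error(curly_G(-0.5, p0))
  expect_error(model_params(a = 0.5))
  expect_error(model_params(gamma = 1.2))
  expect_error(model_params(kappa = 0))
})

test_that("closed forms agree with adaptive quadrature of the definitions", {
  fmono <- function(s) s / (p0$kappa + s)
  ss <- c(0.01, 0.05, 0.2, 0.5, 0.9, 0.99)
  expect_equal(integral_F(ss, p0), integral_F(ss, p0, f = fmono),
               tolerance = 1e-10)
  expect_equal(curly_G(ss, p0), curly_G(ss, p0, f = fmono),
               tolerance = 1e-9)
})

test_that("G has the analytic boundary behaviour", {
  # one-sided derivative at s = 1 equals -gamma / f(1)
  h <- 1e-7
  d1 <- (curly_G(1, p0) - curly_G(1 - h, p0)) / h
  expect_equal(d1, -p0$gamma / reaction_f(1, p0), tolerance = 1e-5)
  # divergence towards s = 0: the decreasing branch of G lies below the
  # interior critical point s_* (about 2.4e-19 at the defaults)
  expect_gt(curly_G(1e-25, p0), curly_G(1e-20, p0))
  expect_gt(curly_G(1e-20, p0), 0)
  expect_gt(curly_G(1e-3, p0), 0)
})

test_that("residual substrate level solves its defining equation", {
  p1 <- model_params(kappa = 1, lam = 0.3)
  s1 <- solve_s_minus_infinity(p1)
  expect_equal(as.numeric(s1), 0.1319, tolerance = 1e-3)
  expect_lt(abs(as.numeric(s1) + 0.3 * integral_F(as.numeric(s1), p1) - 1),
            1e-10)

  s0 <- solve_s_minus_infinity(p0)
  # defaults: astronomically small but representable; log-residual of g = 1
  expect_equal(attr(s0, "log"), -138.1, tolerance = 1e-3)
  u <- attr(s0, "log")
  expect_lt(abs(exp(u) * (1 - p0$lam) - p0$lam * p0$kappa * u - (1 - p0$lam)),
            1e-10)
  # asymptotic formula agrees within 5% (relative, in log-space) for tiny roots
  expect_lt(abs(u - (-(1 - p0$lam) / (p0$kappa * p0$lam))) / abs(u), 0.05)

  expect_error(solve_s_minus_infinity(model_params(lam = 1.5)),
               "non-existence")
})

test_that("nullcline landmarks satisfy their defining identities", {
  er <- existence_report(p0)
  expect_lt(abs(nullcline_ell(er$s_star_hi, p0) - 1), 1e-10)
  # s_star_lo is far below double-grid resolution; verify in log-space
  uls <- log(er$s_star_lo)
  Fv <- 1 - er$s_star_lo - p0$kappa * uls
  expect_lt(abs(er$s_star_lo + p0$lam * Fv - (1 - p0$gamma)), 1e-10)
  expect_true(er$s_star_lo <= er$s_M && er$s_M <= er$s_star_hi)
  expect_gt(nullcline_ell(er$s_M, p0), 1)   # explicit bound holds at defaults

  # monotone up then down around s_M
  sgrid_up <- seq(er$s_M / 100, er$s_M, length.out = 50)
  sgrid_dn <- seq(er$s_M, 1, length.out = 50)
  expect_true(all(diff(nullcline_ell(sgrid_up, p0)) > 0))
  expect_true(all(diff(nullcline_ell(sgrid_dn, p0)) < 0))
})

test_that("existence report classifies the three reference regimes", {
  er <- existence_report(p0)
  expect_true(er$cond_2_13)
  expect_true(er$cond_G_positive)
  expect_true(er$tw_predicted)

  er57 <- existence_report(model_params(lam = 0.57))
  expect_false(er57$cond_2_13)    # explicit bound just fails above 0.56

  erg <- existence_report(model_params(kappa = 1, lam = 0.3, gamma = 0.05))
  expect_false(erg$cond_G_positive)
  expect_false(erg$tw_predicted)

  er15 <- existence_report(model_params(lam = 1.5))
  expect_false(er15$tw_predicted)
  expect_identical(er15$reason, "lambda_ge_1")
})

test_that("G positivity is monotone in gamma at fixed kappa and lambda", {
  gam <- seq(0.05, 0.5, by = 0.05)
  ok <- vapply(gam, function(g) {
    existence_report(model_params(kappa = 1, lam = 0.3, gamma = g))$cond_G_positive
  }, logical(1))
  expect_true(all(diff(as.integer(ok)) >= 0))   # FALSE ... FALSE TRUE ... TRUE
  expect_false(ok[1])
  expect_true(ok[length(ok)])
})

test_that("critical strip width matches brute-force evaluation", {
  for (lam in c(0.3, 0.42, 0.8)) {
    p <- model_params(lam = lam)
    er <- existence_report(p, L = 1)
    expect_equal(er$critical_strip_width,
                 2 * pi / sqrt(2 * reaction_f(1, p) - lam), tolerance = 1e-12)
    expect_true(er$strip_stable)    # L = 1 is below the width in these regimes
  }
  # lambda >= 2 f(1) gives an infinite width (adjust gamma so params validate)
  erInf <- existence_report(model_params(lam = 1.99), L = 100)
  expect_identical(erInf$critical_strip_width, Inf)
})
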