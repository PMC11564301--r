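#' Degenerate biomass diffusivity
#'
#' Evaluates \eqn{D(m) = \delta m^a / (1-m)^b}. The diffusivity degenerates
#' at `m = 0` (producing a sharp, finite wave front) and is singular at
#' `m = 1`, which caps the biomass volume fraction below one.
#'
#' @param m biomass density values in `[0, 1)`.
#' @param p a [model_params()] object.
#' @return Diffusivity values, same length as `m`.
#' @export
diffusion_D <- function(m, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(m < 0 | m >= 1)) stop("diffusion_D: m must lie in [0, 1)")
  p$delta * m^p$a / (1 - m)^p$b
}

#' Monod growth factor
#'
#' Evaluates \eqn{f(s) = s/(\kappa + s)}: saturating substrate uptake with
#' half-saturation `kappa`, so `f(kappa) = 1/2` and `f(0) = 0`.
#'
#' @param s substrate concentration values, `>= 0`.
#' @inheritParams diffusion_D
#' @return Growth factors in `[0, 1)`.
#' @export
reaction_f <- function(s, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(s < 0)) stop("reaction_f: s must be >= 0")
  s / (p$kappa + s)
}

#' Inverse of the Monod function
#'
#' Closed form \eqn{f^{-1}(y) = \kappa y / (1 - y)} for `y` in `(0, 1)`.
#'
#' @param y values in `(0, 1)`.
#' @inheritParams diffusion_D
#' @return Substrate concentrations with `reaction_f(f_inverse(y)) == y`.
#' @export
f_inverse <- function(y, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(y <= 0 | y >= 1)) stop("f_inverse: y must lie in (0, 1)")
  p$kappa * y / (1 - y)
}

#' Accumulated inverse-rate integral F
#'
#' Evaluates \eqn{F(s) = \int_s^1 d\rho / f(\rho)}, which for Monod kinetics
#' has the closed form \eqn{F(s) = 1 - s - \kappa \log s}. `F` is strictly
#' decreasing with `F(1) = 0` and diverges logarithmically as `s -> 0+`.
#' A non-Monod uptake function may be supplied, in which case adaptive
#' quadrature is used.
#'
#' @param s substrate values in `(0, 1]`.
#' @inheritParams diffusion_D
#' @param f optional alternative uptake function `f(s)`; when supplied the
#'   integral is computed by quadrature instead of the Monod closed form.
#' @return Values of `F(s)`.
#' @export
integral_F <- function(s, p, f = NULL) {
  stopifnot(inherits(p, "model_params"))
  if (any(s <= 0)) stop("integral_F: s must be > 0")
  if (any(s > 1)) stop("integral_F: s must be <= 1")
  if (is.null(f)) return(1 - s - p$kappa * log(s))
  vapply(s, function(si) {
    if (si == 1) return(0)
    stats::integrate(function(r) 1 / f(r), si, 1,
                     rel.tol = 1e-12, abs.tol = 1e-12)$value
  }, numeric(1))
}

#' Biomass nullcline
#'
#' Evaluates \eqn{\ell(s) = \gamma^{-1}[(1-s) - \lambda F(s)]}, the curve
#' `m = ell(s)` on which the biomass component of the scaled phase-plane
#' field vanishes. `ell` increases on `(0, s_M)` and decreases on
#' `(s_M, 1)` where `s_M = f_inverse(lam)`, with `ell(1) = 0` and
#' `ell(s) -> -Inf` as `s -> 0+`.
#'
#' @inheritParams integral_F
#' @return Nullcline heights `ell(s)`.
#' @export
nullcline_ell <- function(s, p, f = NULL) {
  ((1 - s) - p$lam * integral_F(s, p, f = f)) / p$gamma
}

# internal: ell evaluated at s = exp(u), stable for astronomically small s
ell_log <- function(u, p) {
  Fv <- 1 - exp(u) - p$kappa * u
  ((1 - exp(u)) - p$lam * Fv) / p$gamma
}

# internal: g(e^u) - c with g(s) = s + lam * F(s), Monod closed form
g_log_minus <- function(u, p, c) {
  exp(u) * (1 - p$lam) + p$lam - p$lam * p$kappa * u - c
}

#' The integral existence functional G
#'
#' Evaluates \eqn{\mathcal{G}(s) = \int_s^1 (\rho + \lambda F(\rho) -
#' (1-\gamma)) \, d\rho / f(\rho)}. Strict positivity of `G` on
#' `(s_minus_inf, 1)` is necessary (and, together with the explicit
#' parameter condition, sufficient) for a travelling wave to exist.
#' For Monod kinetics the closed form
#' \deqn{\mathcal{G}(s) = \kappa(1-s) + (1-s^2)/2 + (\lambda/2)F(s)^2 -
#'   (1-\gamma)F(s)}
#' is used; for a supplied `f`, nested adaptive quadrature.
#'
#' @inheritParams integral_F
#' @return Values of `G(s)`; `G(1) = 0`.
#' @export
curly_G <- function(s, p, f = NULL) {
  stopifnot(inherits(p, "model_params"))
  if (any(s <= 0)) stop("curly_G: s must be > 0")
  if (any(s > 1)) stop("curly_G: s must be <= 1")
  if (is.null(f)) {
    Fv <- 1 - s - p$kappa * log(s)
    return(p$kappa * (1 - s) + (1 - s^2) / 2 +
             p$lam / 2 * Fv^2 - (1 - p$gamma) * Fv)
  }
  vapply(s, function(si) {
    if (si == 1) return(0)
    stats::integrate(function(r) {
      Fr <- integral_F(r, p, f = f)
      (r + p$lam * Fr - (1 - p$gamma)) / f(r)
    }, si, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1))
}

# internal: curly_G at s = exp(u) via the Monod closed form, stable for tiny s
curly_G_log <- function(u, p) {
  s <- exp(u)
  Fv <- 1 - s - p$kappa * u
  p$kappa * (1 - s) + (1 - s^2) / 2 + p$lam / 2 * Fv^2 - (1 - p$gamma) * Fv
}

#' Residual substrate level behind the wave
#'
#' Solves \eqn{g(s) = s + \lambda F(s) = 1} for its nontrivial root
#' \eqn{s_{-\infty} \in (0, 1)}: the substrate concentration left behind a
#' travelling wave. The root can be astronomically small (about `1e-60` for
#' the default parameters), so the equation is solved in log-space
#' (bisection in `u = log s`); if the root underflows double precision the
#' asymptotic value \eqn{\exp(-(1-\lambda)/(\kappa\lambda))} is returned and
#' flagged.
#'
#' @inheritParams diffusion_D
#' @return The root as a numeric scalar, with attributes `log` (its natural
#'   logarithm, always finite) and `asymptotic` (`TRUE` if the returned
#'   value comes from the underflow asymptote).
#' @export
solve_s_minus_infinity <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$lam >= 1)
    stop("no nontrivial root: lambda >= 1 is the non-existence regime")
  if (reaction_f(1, p) <= p$lam)
    stop("no nontrivial root: f(1) <= lambda")
  u_hi <- log(f_inverse(p$lam, p))            # log s_M; g has its minimum at s_M
  u_lo <- -(1 - p$lam) / (p$kappa * p$lam) - 25
  h <- function(u) g_log_minus(u, p, 1)
  if (h(u_hi) >= 0)
    stop("no nontrivial root: g(s_M) >= 1")
  r <- stats::uniroot(h, c(u_lo, u_hi), tol = 1e-13)
  u <- r$root
  s <- exp(u)
  asymptotic <- s == 0
  if (asymptotic) s <- exp(-(1 - p$lam) / (p$kappa * p$lam))  # still underflows
  structure(s, log = u, asymptotic = asymptotic)
}

# internal: extreme roots of ell(s) = 1, i.e. g(s) = 1 - gamma, in log-space.
# Returns c(lo, hi) or c(NA, NA) when the nullcline stays below m = 1.
nullcline_unit_roots <- function(p) {
  sM <- f_inverse(p$lam, p)
  uM <- log(sM)
  gmin <- g_log_minus(uM, p, 0)               # g(s_M)
  target <- 1 - p$gamma
  if (gmin > target) return(c(NA_real_, NA_real_))
  if (gmin == target) return(c(sM, sM))
  # lower branch: g decreasing on (0, s_M); bracket below in log-space
  u_lo <- -(1 - p$lam) / (p$kappa * p$lam) - 25
  lo <- stats::uniroot(function(u) g_log_minus(u, p, target),
                       c(u_lo, uM), tol = 1e-13)$root
  # upper branch: g increasing on (s_M, 1), g(1) = 1 > 1 - gamma
  hi <- stats::uniroot(function(s) s + p$lam * integral_F(s, p) - target,
                       c(sM, 1), tol = 1e-14)$root
  c(exp(lo), hi)
}

# internal: minimum of curly_G over (s_minus_inf, 1).
# The interior minimiser is the lower root s_* of g(s) = 1 - gamma (where
# G' changes sign); when that root does not exist G decreases monotonically
# to G(1) = 0 and the minimum is the grid value nearest s = 1.
curly_G_min <- function(p, u_minf, n_grid = 2048) {
  roots <- nullcline_unit_roots(p)
  u_lo <- max(u_minf, log(1e-12))
  us <- seq(u_lo, log(1 - 1e-6), length.out = n_grid)
  vals <- curly_G_log(us, p)
  i <- which.min(vals)
  gmin <- vals[i]
  # golden-section refinement around the grid minimum
  a <- us[max(1, i - 1)]; b <- us[min(n_grid, i + 1)]
  if (b > a) {
    opt <- stats::optimize(function(u) curly_G_log(u, p), c(a, b))
    gmin <- min(gmin, opt$objective)
  }
  if (!is.na(roots[1])) {
    # evaluate at the exact interior critical point (can be far below 1e-12)
    u_star <- log(roots[1])
    if (u_star > u_minf) gmin <- min(gmin, curly_G_log(u_star, p))
  }
  gmin
}

#' Travelling-wave existence report
#'
#' Computes the phase-plane landmarks and the two existence conditions for
#' a travelling wave of the biofilm model:
#' * Condition "2.13" (explicit sufficient parameter bound): for Monod
#'   kinetics, \eqn{\gamma + \lambda + \kappa\lambda(1 - \log(\kappa\lambda/
#'   (1-\lambda))) \le 1}.
#' * Positivity of the integral functional: \eqn{\mathcal{G}(s) > 0} on
#'   \eqn{(s_{-\infty}, 1)} (necessary for existence).
#'
#' The landmarks are the residual substrate level `s_minus_inf`, the
#' nullcline maximiser `s_M = f_inverse(lam)`, and the extreme roots
#' `s_star_lo <= s_M <= s_star_hi` of `ell(s) = 1` (present only when the
#' explicit bound holds). The minimum of `G` is found on a dense log-spaced
#' grid refined by local minimisation, with the exact interior critical
#' point (the lower root of `g(s) = 1 - gamma`, which can lie far below
#' double-precision grid resolution) always included as a candidate.
#'
#' For `lam >= 1` no wave exists regardless of the other parameters and the
#' report says so with `reason = "lambda_ge_1"`.
#'
#' @inheritParams diffusion_D
#' @param L optional transverse strip width; when given, the report states
#'   whether `L` is below the critical width \eqn{2\pi/\sqrt{2 f(1) -
#'   \lambda}} under which transverse perturbation modes decay.
#' @return An object of class `existence_report`.
#' @examples
#' existence_report(model_params())
#' @export
existence_report <- function(p, L = NULL) {
  stopifnot(inherits(p, "model_params"))
  f1 <- reaction_f(1, p)
  strip <- if (2 * f1 > p$lam) 2 * pi / sqrt(2 * f1 - p$lam) else Inf

  if (p$lam >= 1) {
    rep <- list(params = p, s_minus_inf = NA_real_, log_s_minus_inf = NA_real_,
                s_M = NA_real_, s_star_lo = NA_real_, s_star_hi = NA_real_,
                G_min = NA_real_, cond_2_13 = FALSE, cond_G_positive = FALSE,
                tw_predicted = FALSE, reason = "lambda_ge_1",
                critical_strip_width = strip, L = L,
                strip_stable = if (is.null(L)) NA else L < strip)
    return(structure(rep, class = "existence_report"))
  }

  sminf <- solve_s_minus_infinity(p)
  u_minf <- attr(sminf, "log")
  sM <- f_inverse(p$lam, p)
  lhs_2_14 <- p$gamma + p$lam +
    p$kappa * p$lam * (1 - log(p$kappa * p$lam / (1 - p$lam)))
  cond1 <- lhs_2_14 <= 1
  roots <- nullcline_unit_roots(p)
  Gmin <- curly_G_min(p, u_minf)
  condG <- Gmin > 0

  rep <- list(params = p,
              s_minus_inf = as.numeric(sminf),
              log_s_minus_inf = u_minf,
              s_M = sM, s_star_lo = roots[1], s_star_hi = roots[2],
              G_min = Gmin,
              cond_2_13 = cond1, cond_G_positive = condG,
              tw_predicted = cond1 && condG,
              reason = if (cond1 && condG) "conditions_met"
                       else if (!condG) "G_not_positive" else "cond_2_13_violated",
              critical_strip_width = strip, L = L,
              strip_stable = if (is.null(L)) NA else L < strip)
  structure(rep, class = "existence_report")
}

#' @method print existence_report
#' @export
print.existence_report <- function(x, ...) {
  cat("Travelling-wave existence report\n")
  if (identical(x$reason, "lambda_ge_1")) {
    cat("  lambda >= 1: no travelling wave exists in this regime\n")
  } else {
    if (is.finite(x$s_minus_inf) && x$s_minus_inf > 0) {
      cat(sprintf("  s_-inf = %.6g   (log s_-inf = %.4f)\n",
                  x$s_minus_inf, x$log_s_minus_inf))
    } else {
      cat(sprintf("  s_-inf underflows; log s_-inf = %.4f\n", x$log_s_minus_inf))
    }
    cat(sprintf("  s_M = %.6g   s_* = %.6g   s^* = %.6g\n",
                x$s_M, x$s_star_lo, x$s_star_hi))
    cat(sprintf("  min G = %.6g\n", x$G_min))
    cat(sprintf("  explicit parameter bound satisfied: %s\n", x$cond_2_13))
    cat(sprintf("  G positive on (s_-inf, 1):          %s\n", x$cond_G_positive))
  }
  cat(sprintf("  travelling wave predicted: %s (%s)\n", x$tw_predicted, x$reason))
  cat(sprintf("  critical transverse strip width: %.6g\n", x$critical_strip_width))
  if (!is.null(x$L))
    cat(sprintf("  strip width L = %g: transverse modes %s\n", x$L,
                if (isTRUE(x$strip_stable)) "decay" else "not guaranteed to decay"))
  invisible(x)
}

#' Consumption-rate threshold for positivity of G
#'
#' The smallest `gamma` at which \eqn{\mathcal{G}(s) > 0} holds on all of
#' \eqn{(s_{-\infty}, 1)} at fixed `lam` and `kappa`: the bifurcation
#' boundary below which no travelling wave exists. Located by root-finding
#' on the minimum of `G` (which is monotone in `gamma`).
#'
#' @param lam cell-loss rate in `(0, 1)`.
#' @param kappa Monod half-saturation constant.
#' @param interval search interval for the threshold.
#' @return The threshold value of `gamma`.
#' @export
gamma_positivity_threshold <- function(lam, kappa, interval = c(0.02, 0.9)) {
  f <- function(g) {
    p <- model_params(kappa = kappa, gamma = g, lam = lam)
    curly_G_min(p, attr(solve_s_minus_infinity(p), "log"))
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Cell-loss-rate boundaries of the two existence conditions
#'
#' Scans `lam` over a uniform grid at fixed `gamma` and `kappa` and
#' reports the boundary of each travelling-wave existence condition:
#' the smallest grid `lam` for which \eqn{\mathcal{G} > 0} on
#' \eqn{(s_{-\infty}, 1)} (the integral condition, also necessary), and
#' the largest grid `lam` satisfying the explicit parameter bound
#' \eqn{\gamma + \lambda + \kappa\lambda(1 - \log(\kappa\lambda/(1-\lambda)))
#' \le 1}.
#'
#' @param gamma consumption rate.
#' @param kappa Monod half-saturation constant.
#' @param step grid step for `lam` (default `0.01`).
#' @return A list with `cond1_lambda_min` and `cond2_lambda_max`.
#' @export
condition_lambda_boundaries <- function(gamma, kappa, step = 0.01) {
  lams <- seq(step, 1 - step, by = step)
  f1 <- 1 / (1 + kappa)
  g_ok <- vapply(lams, function(l) {
    if (l >= f1) return(FALSE)
    p <- model_params(kappa = kappa, gamma = gamma, lam = l)
    curly_G_min(p, attr(solve_s_minus_infinity(p), "log")) > 0
  }, logical(1))
  c2 <- vapply(lams, function(l) {
    gamma + l + kappa * l * (1 - log(kappa * l / (1 - l))) <= 1
  }, logical(1))
  list(cond1_lambda_min = if (any(g_ok)) min(lams[g_ok]) else NA_real_,
       cond2_lambda_max = if (any(c2)) max(lams[c2]) else NA_real_)
}
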