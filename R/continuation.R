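#' Continuation solver configuration
#'
#' Settings for the heteroclinic two-point boundary-value solver. The
#' connection between the rest states `(0, s_minus_inf)` and `(0, 1)` is
#' computed by single shooting on the rescaled system
#' \deqn{M' = v T [\ell(S) - M], \quad S' = (\gamma/v) T f(S) M D(M),
#'   \quad \tau \in (0, 1),}
#' launched on the centre-unstable manifold at `(eps0, s_eps0)` (with
#' `s_eps0` the smallest root of `ell(s) = eps0`) and required to land at
#' `(eps1, 1)`. The wave speed `v` and the traversal time `T` are the two
#' shooting unknowns matching the two terminal conditions.
#'
#' @param eps0 launch biomass offset at the substrate-depleted end
#'   (default `1e-3`).
#' @param eps1 terminal biomass at the `s = 1` end (default `1e-3`).
#' @param newton_tol tolerance on the terminal substrate mismatch
#'   (default `1e-2`). With endpoints truncated at `eps0`/`eps1` the
#'   mismatch cannot fall below about `eps1 / |ell'(1)|` (see
#'   [solve_connection()] details), so the tolerance must sit above that
#'   scale; the wave speed itself is resolved to the bisection tolerance
#'   regardless.
#' @param newton_maxiter damped-Newton iteration cap (default `30`).
#' @param gamma_grid consumption-rate sweep values for [sweep_gamma()].
#' @param init_v,init_T starting guesses for the first solve.
#' @param rel_tol,step_cap,max_steps adaptive integrator controls (as in
#'   [solver_config()]).
#' @return An object of class `continuation_config`.
#' @export
continuation_config <- function(eps0 = 1e-3, eps1 = 1e-3,
                                newton_tol = 1e-2, newton_maxiter = 30L,
                                gamma_grid = NULL,
                                init_v = NULL, init_T = NULL,
                                rel_tol = 1e-8, step_cap = 1e-3,
                                max_steps = 4e6L) {
  stopifnot(eps0 > 0, eps0 <= 0.05, eps1 > 0, eps1 <= 0.05,
            newton_tol > 0, newton_maxiter >= 1)
  if (!is.null(gamma_grid)) stopifnot(all(gamma_grid > 0 & gamma_grid < 1))
  structure(list(eps0 = eps0, eps1 = eps1, newton_tol = newton_tol,
                 newton_maxiter = as.integer(newton_maxiter),
                 gamma_grid = gamma_grid, init_v = init_v, init_T = init_T,
                 rel_tol = rel_tol, step_cap = step_cap,
                 max_steps = as.integer(max_steps)),
            class = "continuation_config")
}

#' Launch point on the centre-unstable manifold
#'
#' The manifold of the rest state `(0, s_minus_inf)` is well approximated
#' by the nullcline `(ell(s), s)` near the rest state, so the shooting
#' orbit is launched at `(eps0, s_eps0)` with `s_eps0` the smallest root of
#' `ell(s) = eps0`, found by bracketed root-finding on the increasing
#' nullcline branch `(s_minus_inf, s_M)` in log-space.
#'
#' @param eps0 launch biomass offset.
#' @param p a [model_params()] object.
#' @return Named vector `c(M = eps0, S = s_eps0)`.
#' @export
launch_point <- function(eps0, p) {
  stopifnot(inherits(p, "model_params"), eps0 > 0)
  sm <- solve_s_minus_infinity(p)
  u_lo <- attr(sm, "log")
  u_hi <- log(f_inverse(p$lam, p))
  if (ell_log(u_hi, p) < eps0)
    stop("launch_point: no root, eps0 exceeds the nullcline maximum ",
         signif(ell_log(u_hi, p), 6))
  u <- stats::uniroot(function(u) ell_log(u, p) - eps0,
                      c(u_lo, u_hi), tol = 1e-14)$root
  c(M = eps0, S = exp(u))
}

#' Shooting residual of the boundary-value problem
#'
#' Integrates the rescaled connection system over `tau` in `[0, 1]` from
#' [launch_point()] with the adaptive RK4 integrator and returns the
#' terminal mismatch `c(M(1) - eps1, S(1) - 1)`. Blow-up during the
#' integration (biomass reaching the density cap, or substrate overshooting
#' 1) is returned as a large penalty residual flagged via the `"flag"`
#' attribute, so that the Newton driver can back off.
#'
#' @param v wave speed (> 0).
#' @param T traversal-time scaling (> 0).
#' @param gamma consumption rate used for this solve (overrides `p$gamma`).
#' @inheritParams launch_point
#' @param cfg a [continuation_config()] object.
#' @return Residual vector of length 2 (attribute `flag`: 0 for a clean
#'   integration).
#' @export
shooting_residual <- function(v, T, gamma, p, cfg = continuation_config()) {
  stopifnot(inherits(p, "model_params"), inherits(cfg, "continuation_config"))
  if (v <= 0 || T <= 0) stop("shooting_residual: v and T must be > 0")
  p2 <- model_params(delta = p$delta, a = p$a, b = p$b, kappa = p$kappa,
                     gamma = gamma, lam = p$lam)
  lp <- launch_point(cfg$eps0, p2)
  out <- integrate_shooting_cpp(v, T, pars_vec(p2), lp[["M"]], lp[["S"]],
                                cfg$rel_tol, cfg$step_cap, cfg$max_steps,
                                FALSE)
  if (out$flag != 0) {
    res <- c(10, 10)
  } else {
    res <- c(out$m_end - cfg$eps1, out$s_end - 1)
  }
  attr(res, "flag") <- out$flag
  res
}

#' Measure a consistent traversal-time guess
#'
#' Integrates the (un-rescaled) phase-plane field forward from
#' [launch_point()] at a given speed until the substrate reaches 1 and
#' returns the elapsed scaled time. Near the degenerate rest state the
#' orbit crawls (the biomass mobility `M D(M)` is tiny at the launch
#' offset), so the traversal time can be many orders of magnitude larger
#' than the visible width of the wave; measuring it is far more reliable
#' than guessing.
#'
#' @inheritParams shooting_residual
#' @return The elapsed scaled time (attribute `flag` as in the
#'   integrator: 0 means the substrate level 1 was reached).
#' @export
measure_traversal_time <- function(v, gamma, p, cfg = continuation_config()) {
  p2 <- model_params(delta = p$delta, a = p$a, b = p$b, kappa = p$kappa,
                     gamma = gamma, lam = p$lam)
  lp <- launch_point(cfg$eps0, p2)
  out <- integrate_phase_cpp(v, pars_vec(p2), lp[["M"]], lp[["S"]],
                             1 - 1e-12, cfg$eps1, cfg$rel_tol, cfg$step_cap,
                             1e300, cfg$max_steps)
  structure(out$tau_end, flag = out$flag)
}

#' Solve one heteroclinic connection
#'
#' Damped Newton iteration (finite-difference Jacobian, in the logarithms
#' of the unknowns to keep them positive) on the 2x2 shooting system
#' `shooting_residual(v, T) = 0`. The shooting system has a spurious
#' residual-zero family at vanishing `v T` (the biomass component simply
#' never leaves the launch offset while the substrate equilibrates), so a
#' converged point whose orbit never rises above the launch scale is
#' reported with `converged = FALSE` and `reason = "spurious"`.
#'
#' @details
#' The two-equation system is solved by an integrate-to-event bisection on
#' the speed. For a given `v` the orbit is integrated from the launch
#' point until the biomass falls back through `eps1` (the field is
#' perfectly regular slightly beyond `s = 1`, so the orbit may overshoot
#' the substrate boundary); the substrate level `s_end` at that crossing
#' classifies the speed: forward orbits order inversely with `v`, so slow
#' speeds carry the biomass past `s = 1` (`s_end >= 1`) and fast speeds
#' drop it early (`s_end < 1`). The connection sits at the separating
#' speed, `T` is the measured traversal time there, and the reported
#' residual is the terminal substrate mismatch `|s_end - 1|`.
#'
#' Because the traversal time is long and the linearisation around the
#' connection is strongly expanding, single shooting cannot reduce the
#' terminal mismatch below the endpoint-truncation scale
#' `eps1 / |ell'(1)|` (the orbit relaxes onto the nullcline and slides
#' into the rest state): the speed is nonetheless resolved to the
#' bisection tolerance. The default `newton_tol` therefore sits above the
#' truncation scale; it guards against bracket failures and the spurious
#' small-`v T` family (reported with `reason = "spurious"`), not against
#' the truncation itself.
#'
#' @inheritParams shooting_residual
#' @param guess numeric `c(v, T)` starting point; the speed component
#'   seeds the bracket search and `T` (which may be `NA`) is re-measured
#'   at the converged speed.
#' @return An object of class `continuation_point`: `gamma`, `v`, `T`,
#'   `orbit` (the converged trajectory on `[0, 1]`), `converged`,
#'   `residual_norm` (terminal substrate mismatch at the returned speed),
#'   `fixed_tau_residual` (the [shooting_residual()] of the returned
#'   `(v, T)` pair, as a cross-check), `n_iter` (orbit integrations).
#' @export
solve_connection <- function(gamma, p, cfg = continuation_config(),
                             guess) {
  stopifnot(length(guess) == 2, guess[1] > 0)
  p2 <- model_params(delta = p$delta, a = p$a, b = p$b, kappa = p$kappa,
                     gamma = gamma, lam = p$lam)
  lp <- launch_point(cfg$eps0, p2)
  n_eval <- 0L
  shoot <- function(v) {
    n_eval <<- n_eval + 1L
    out <- integrate_phase_cpp(v, pars_vec(p2), lp[["M"]], lp[["S"]],
                               2, cfg$eps1, cfg$rel_tol, cfg$step_cap,
                               1e300, cfg$max_steps)
    if (out$flag == 3)
      stop("solve_connection: integration budget exhausted at v = ", v)
    # TRUE = slow (biomass carried past s = 1, or never shed at all)
    slow <- !((out$flag == 4 || out$flag == 2) && out$armed && out$s_end < 1)
    list(slow = slow, s_end = out$s_end, tau = out$tau_end,
         armed = out$armed, flag = out$flag)
  }
  v0 <- guess[1]
  ok <- TRUE
  sh0 <- tryCatch(shoot(v0), error = function(e) NULL)
  if (is.null(sh0)) ok <- FALSE
  v_lo <- NA_real_; v_hi <- NA_real_
  if (ok) {
    if (sh0$slow) v_lo <- v0 else v_hi <- v0
    v <- v0
    for (k in 1:80) {
      v <- if (sh0$slow) v * 1.3 else v / 1.3
      shk <- tryCatch(shoot(v), error = function(e) NULL)
      if (is.null(shk)) { ok <- FALSE; break }
      if (shk$slow != sh0$slow) {
        if (shk$slow) v_lo <- v else v_hi <- v
        break
      }
      if (shk$slow) v_lo <- v else v_hi <- v
      if (k == 80) ok <- FALSE
    }
  }
  if (ok && (!is.finite(v_lo) || !is.finite(v_hi))) ok <- FALSE
  if (ok) {
    while ((v_hi - v_lo) > 1e-7 * v_hi) {
      v <- sqrt(v_lo * v_hi)
      shk <- shoot(v)
      if (shk$slow) v_lo <- v else v_hi <- v
    }
    v <- sqrt(v_lo * v_hi)
  } else {
    v <- v0
  }
  fin <- tryCatch(shoot(v), error = function(e) NULL)
  T <- if (!is.null(fin)) fin$tau else guess[2]
  rn <- if (!is.null(fin)) abs(fin$s_end - 1) else 10
  fixed_tau_res <- if (ok && !is.null(fin) && is.finite(T) && T > 0)
    shooting_residual(v, T, gamma, p, cfg) else c(10, 10)
  converged <- ok && rn < cfg$newton_tol
  orb <- if (is.finite(T) && T > 0) {
    integrate_shooting_cpp(v, T, pars_vec(p2), lp[["M"]], lp[["S"]],
                           cfg$rel_tol, cfg$step_cap, cfg$max_steps, TRUE)
  } else list(tau = 0, M = lp[["M"]], S = lp[["S"]])
  reason <- if (!ok) "no_bracket" else "ok"
  if (converged && max(orb$M) < 10 * cfg$eps1) {
    converged <- FALSE
    reason <- "spurious"
  }
  structure(list(gamma = gamma, v = v, T = T,
                 orbit = list(tau = orb$tau, M = orb$M, S = orb$S),
                 converged = converged, residual_norm = rn,
                 fixed_tau_residual = fixed_tau_res,
                 n_iter = n_eval, reason = reason),
            class = "continuation_point")
}

#' @method print continuation_point
#' @export
print.continuation_point <- function(x, ...) {
  cat(sprintf("Heteroclinic connection at gamma = %g: v = %.6g, T = %.6g (%s, |r| = %.2g)\n",
              x$gamma, x$v, x$T,
              if (x$converged) "converged" else "NOT converged",
              x$residual_norm))
  invisible(x)
}

#' Sweep the consumption rate and trace the bifurcation curve
#'
#' Marches through `cfg$gamma_grid`, solving the connection at each value
#' with a secant predictor in `(log v, log T)` from the previous two
#' converged points. The sweep stops at the first failure, recording the
#' failure boundary: along a sweep towards small `gamma` this brackets the
#' non-existence threshold where the integral functional loses positivity.
#'
#' @inheritParams shooting_residual
#' @return A list of `continuation_point`s (class `continuation_sweep`),
#'   with attribute `failure_gamma` (`NA` if all points converged).
#' @export
sweep_gamma <- function(p, cfg) {
  stopifnot(inherits(cfg, "continuation_config"))
  if (is.null(cfg$gamma_grid)) stop("cfg$gamma_grid must be set")
  if (is.null(cfg$init_v))
    stop("cfg$init_v must be set for the first point")
  if (is.null(cfg$init_T)) cfg$init_T <- NA_real_
  grid <- cfg$gamma_grid
  pts <- list()
  zprev <- NULL; zprev2 <- NULL
  failure <- NA_real_
  for (k in seq_along(grid)) {
    guess <- if (!is.null(zprev) && !is.null(zprev2)) {
      exp(2 * zprev - zprev2)                       # secant predictor
    } else if (!is.null(zprev)) {
      exp(zprev)
    } else c(cfg$init_v, cfg$init_T)
    pt <- solve_connection(grid[k], p, cfg, guess)
    if (!pt$converged) {
      if (k == 1) stop("sweep_gamma: first point failed to converge; ",
                       "improve init_v/init_T")
      failure <- grid[k]
      break
    }
    pts[[length(pts) + 1L]] <- pt
    zprev2 <- zprev
    zprev <- log(c(pt$v, pt$T))
  }
  structure(pts, class = c("continuation_sweep", "list"),
            failure_gamma = failure)
}
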