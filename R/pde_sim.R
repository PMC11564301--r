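#' Finite-volume simulation configuration
#'
#' Discretisation and run parameters for the 1D/2D finite-volume solver.
#' The reference discretisation of the unit interval uses
#' `dx = 2^-N` and `dt = 1e-2 * (2^9 * dx)^2`, seeds a quartic biomass
#' colony of extent `d = 5/127` and height `h = 0.1`, and tracks the
#' front as the largest `x` with `M > 1e-2`.
#'
#' @param H domain length in `x` (> 0).
#' @param L domain width in `y` (2D runs only; `NULL` for 1D).
#' @param dx,dy cell sizes (defaults `2^-10`; `dy = dx`).
#' @param dt time step; default follows the reference scaling
#'   `1e-2 * (2^9 * dx)^2`.
#' @param t_end final simulation time.
#' @param snapshot_times output times; default an even grid of 31 times
#'   from 0 to `t_end`.
#' @param d initial colony extent (default `5/127`).
#' @param h initial colony height (default `0.1`).
#' @param fp_tol max-norm tolerance of the Picard (fixed-point) iteration
#'   per time step (default `1e-9`).
#' @param fp_maxiter Picard iteration cap (default `200`).
#' @param front_threshold biomass level defining the wave interface
#'   (default `1e-2`).
#' @param fit_window fraction of the snapshot series (from the end) used
#'   for the linear wave-speed fit (default `0.6`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(H = 1, L = NULL, dx = 2^-10, dy = dx,
                       dt = 1e-2 * (2^9 * dx)^2, t_end = 60,
                       snapshot_times = NULL, d = 5 / 127, h = 0.1,
                       fp_tol = 1e-9, fp_maxiter = 200L,
                       front_threshold = 1e-2, fit_window = 0.6) {
  stopifnot(H > 0, dx > 0, dt > 0, t_end > 0, d > 0, d < H, h > 0, h < 1,
            fp_tol > 0, front_threshold > 0, front_threshold < h,
            fit_window > 0, fit_window <= 1)
  if (!is.null(L)) stopifnot(L > 0, dy > 0)
  if (is.null(snapshot_times))
    snapshot_times <- seq(0, t_end, length.out = 31)
  structure(list(H = H, L = L, dx = dx, dy = dy, dt = dt, t_end = t_end,
                 snapshot_times = sort(unique(snapshot_times)),
                 d = d, h = h, fp_tol = fp_tol,
                 fp_maxiter = as.integer(fp_maxiter),
                 front_threshold = front_threshold, fit_window = fit_window),
            class = "sim_config")
}

# internal: cell centres
cell_centres <- function(len, dcell) seq(dcell / 2, len - dcell / 2, by = dcell)

new_field_state <- function(t, M, S, x, dx, y = NULL, dy = NULL) {
  structure(list(t = t, M = M, S = S, x = x, dx = dx, y = y, dy = dy,
                 nx = length(x), ny = if (is.null(y)) NULL else length(y)),
            class = "field_state")
}

#' @method print field_state
#' @export
print.field_state <- function(x, ...) {
  dims <- if (is.null(x$ny)) sprintf("%d cells", x$nx)
          else sprintf("%d x %d cells", x$nx, x$ny)
  cat(sprintf("Field state at t = %g (%s): max M = %.4g, min S = %.4g\n",
              x$t, dims, max(x$M), min(x$S)))
  invisible(x)
}

#' Quartic colony initial condition (1D)
#'
#' Biomass `M(x, 0) = h (1 - x^4/d^4)` for `x <= d`, zero beyond; substrate
#' `S` identically 1. Evaluated at cell centres.
#'
#' @param cfg a [sim_config()] object.
#' @return A `field_state`.
#' @export
initial_condition_1d <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- cell_centres(cfg$H, cfg$dx)
  M <- ifelse(x <= cfg$d, cfg$h * (1 - x^4 / cfg$d^4), 0)
  new_field_state(0, M, rep(1, length(x)), x, cfg$dx)
}

#' Quartic colony with cosine transverse modulation (2D)
#'
#' Tensor initial condition
#' `M(x, y, 0) = h (1 - x^4/d^4) (1 + cos(2 pi y / L)/5)` for `x <= d`,
#' zero beyond; `S` identically 1.
#'
#' @inheritParams initial_condition_1d
#' @return A `field_state` with matrix fields (`nx` rows, `ny` columns).
#' @export
initial_condition_2d <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$L)) stop("initial_condition_2d: cfg$L must be set")
  x <- cell_centres(cfg$H, cfg$dx)
  y <- cell_centres(cfg$L, cfg$dy)
  mx <- ifelse(x <= cfg$d, cfg$h * (1 - x^4 / cfg$d^4), 0)
  M <- outer(mx, 1 + cos(2 * pi * y / cfg$L) / 5)
  new_field_state(0, M, matrix(1, length(x), length(y)), x, cfg$dx, y, cfg$dy)
}

#' Advance the fields by one trapezoidal step
#'
#' One step of the trapezoidal (Crank-Nicolson) rule applied to the
#' two-point flux-approximation finite-volume semi-discretisation, with
#' arithmetic-mean face diffusivities, zero-flux boundaries, and a Picard
#' iteration (lagged diffusivity and reaction factors) for the coupled
#' nonlinear update.
#'
#' @param state a `field_state`.
#' @inheritParams initial_condition_1d
#' @param p a [model_params()] object.
#' @param reactions set `FALSE` to switch the reaction terms off (pure
#'   degenerate diffusion; used to verify exact mass conservation).
#' @return The advanced `field_state`.
#' @export
step_trapezoidal <- function(state, cfg, p, reactions = TRUE) {
  stopifnot(inherits(state, "field_state"), inherits(cfg, "sim_config"),
            inherits(p, "model_params"))
  if (is.null(state$ny)) {
    out <- run_pde1d_cpp(state$M, state$S, state$dx, cfg$dt, pars_vec(p),
                         cfg$fp_tol, cfg$fp_maxiter, reactions, 1L,
                         integer(0))
    new_field_state(state$t + cfg$dt, out$M_final, out$S_final,
                    state$x, state$dx)
  } else {
    st <- step_pde2d(state, cfg, p, reactions)
    st
  }
}

# internal: one 2D trapezoidal step (sparse implicit Picard iteration)
step_pde2d <- function(state, cfg, p, reactions = TRUE) {
  nx <- state$nx; ny <- state$ny
  dx <- state$dx; dy <- state$dy; dt <- cfg$dt
  M <- state$M; S <- state$S
  n <- nx * ny
  Dsafe <- function(m) p$delta * pmin(pmax(m, 0), 1 - 1e-9)^p$a /
    (1 - pmin(pmax(m, 0), 1 - 1e-9))^p$b
  fsafe <- function(s) pmax(s, 0) / (p$kappa + pmax(s, 0))

  # explicit operator at the old level
  apply_op <- function(Mm, Ss, react) {
    Dm <- Dsafe(Mm)
    Fx <- matrix(0, nx + 1, ny)                 # x-face fluxes D dM/dx
    Fx[2:nx, ] <- 0.5 * (Dm[-nx, ] + Dm[-1, ]) * (Mm[-1, ] - Mm[-nx, ]) / dx
    Fy <- matrix(0, nx, ny + 1)
    Fy[, 2:ny] <- 0.5 * (Dm[, -ny] + Dm[, -1]) * (Mm[, -1] - Mm[, -ny]) / dy
    div <- (Fx[-1, ] - Fx[-(nx + 1), ]) / dx + (Fy[, -1] - Fy[, -(ny + 1)]) / dy
    if (react) div + (fsafe(Ss) - p$lam) * Mm else div
  }
  rhs <- M + 0.5 * dt * apply_op(M, S, reactions)

  idx <- function(i, j) i + (j - 1L) * nx
  ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
  Mk <- M; Sk <- S
  for (it in seq_len(cfg$fp_maxiter)) {
    Dm <- Dsafe(Mk)
    DW <- matrix(0, nx, ny); DE <- matrix(0, nx, ny)
    DS_ <- matrix(0, nx, ny); DN <- matrix(0, nx, ny)
    DW[2:nx, ] <- 0.5 * (Dm[-nx, ] + Dm[-1, ]); DE[1:(nx - 1), ] <- DW[2:nx, ]
    DS_[, 2:ny] <- 0.5 * (Dm[, -ny] + Dm[, -1]); DN[, 1:(ny - 1)] <- DS_[, 2:ny]
    rk <- if (reactions) fsafe(Sk) - p$lam else matrix(0, nx, ny)
    cx <- 0.5 * dt / dx^2; cy <- 0.5 * dt / dy^2
    diagv <- 1 + cx * (DW + DE) + cy * (DS_ + DN) - 0.5 * dt * rk

    rows <- c(idx(ii, jj),
              idx(ii[ii > 1], jj[ii > 1]),
              idx(ii[ii < nx], jj[ii < nx]),
              idx(ii[jj > 1], jj[jj > 1]),
              idx(ii[jj < ny], jj[jj < ny]))
    cols <- c(idx(ii, jj),
              idx(ii[ii > 1] - 1L, jj[ii > 1]),
              idx(ii[ii < nx] + 1L, jj[ii < nx]),
              idx(ii[jj > 1], jj[jj > 1] - 1L),
              idx(ii[jj < ny], jj[jj < ny] + 1L))
    vals <- c(as.vector(diagv),
              -cx * DW[cbind(ii[ii > 1], jj[ii > 1])],
              -cx * DE[cbind(ii[ii < nx], jj[ii < nx])],
              -cy * DS_[cbind(ii[jj > 1], jj[jj > 1])],
              -cy * DN[cbind(ii[jj < ny], jj[jj < ny])])
    A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
    Mnew <- matrix(as.numeric(Matrix::solve(A, as.vector(rhs))), nx, ny)
    if (reactions) {
      Snew <- S - 0.5 * dt * p$gamma *
        (fsafe(Sk) * pmax(Mnew, 0) + fsafe(S) * pmax(M, 0))
      Snew[Snew < 0] <- 0
    } else Snew <- S
    inc <- max(abs(Mnew - Mk), abs(Snew - Sk))
    Mk <- Mnew; Sk <- Snew
    if (inc < cfg$fp_tol) break
    if (it == cfg$fp_maxiter)
      stop("2D fixed-point iteration failed to converge; reduce dt")
  }
  if (max(Mk) > 1 - 1e-6)
    stop("biomass density reached the singular value; refine the grid/time step")
  new_field_state(state$t + dt, Mk, Sk, state$x, dx, state$y, dy)
}

#' Run the finite-volume simulation
#'
#' Repeatedly applies the trapezoidal step and collects snapshots at the
#' configured output times (rounded to whole steps).
#'
#' @inheritParams step_trapezoidal
#' @param ic initial `field_state`; default built by
#'   [initial_condition_1d()] or [initial_condition_2d()] depending on
#'   whether `cfg$L` is set.
#' @return A list of `field_state` snapshots (class `sim_snapshots`), with
#'   attribute `fp_iters` summarising the Picard iteration counts.
#' @export
simulate_pde <- function(cfg, p, ic = NULL, reactions = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(p, "model_params"))
  if (is.null(ic))
    ic <- if (is.null(cfg$L)) initial_condition_1d(cfg) else initial_condition_2d(cfg)
  stopifnot(inherits(ic, "field_state"))
  steps_at <- unique(pmax(0L, as.integer(round(cfg$snapshot_times / cfg$dt))))
  nsteps <- max(steps_at)
  if (is.null(ic$ny)) {
    out <- run_pde1d_cpp(ic$M, ic$S, ic$dx, cfg$dt, pars_vec(p),
                         cfg$fp_tol, cfg$fp_maxiter, reactions,
                         nsteps, steps_at)
    snaps <- lapply(seq_along(steps_at), function(k) {
      new_field_state(steps_at[k] * cfg$dt, out$M[k, ], out$S[k, ],
                      ic$x, ic$dx)
    })
    attr(snaps, "fp_iters") <- c(total = out$total_fp_iters,
                                 max = out$max_fp_iters)
  } else {
    snaps <- vector("list", length(steps_at))
    st <- ic
    done <- 0L
    for (k in seq_along(steps_at)) {
      while (done < steps_at[k]) {
        st <- step_pde2d(st, cfg, p, reactions)
        done <- done + 1L
      }
      snaps[[k]] <- st
    }
  }
  class(snaps) <- c("sim_snapshots", "list")
  snaps
}

# internal: interface position (largest cell-centre x with M above threshold);
# 2D states use the y-averaged profile.
interface_position <- function(state, threshold) {
  prof <- if (is.null(state$ny)) state$M else rowMeans(state$M)
  hit <- which(prof > threshold)
  if (length(hit) == 0) return(NA_real_)
  state$x[max(hit)]
}

#' Wave speed from front tracking
#'
#' Computes the interface (largest `x` with `M > front_threshold`, on the
#' y-averaged profile in 2D) for each snapshot and fits an ordinary
#' least-squares line through `(t, interface)` over the fit window: the
#' trailing `fit_window` fraction of snapshots, excluding any snapshot
#' before the interface has moved at least five cells from its initial
#' position.
#'
#' @param snapshots a [simulate_pde()] result.
#' @inheritParams initial_condition_1d
#' @return An object of class `wave_speed_fit` with `times`, `interface`,
#'   `slope` (the estimated speed), `intercept` and `rms_residual`.
#' @export
estimate_wave_speed <- function(snapshots, cfg) {
  stopifnot(inherits(snapshots, "sim_snapshots"), inherits(cfg, "sim_config"))
  times <- vapply(snapshots, function(s) s$t, numeric(1))
  pos <- vapply(snapshots, interface_position, numeric(1),
                threshold = cfg$front_threshold)
  if (any(is.na(pos))) stop("interface not defined in some snapshots")
  nlast <- length(snapshots[[1]]$x)
  moved <- pos - pos[1] >= 5 * cfg$dx
  i0 <- max(which(!moved), 0L) + 1L
  iwin <- max(i0, ceiling(length(times) * (1 - cfg$fit_window)) + 1L)
  sel <- seq(iwin, length(times))
  if (length(sel) < 10)
    stop("fewer than 10 snapshots in the fit window")
  if (any(pos[sel] >= snapshots[[1]]$x[nlast]))
    stop("interface reached the right boundary during the fit window; ",
         "domain too short")
  fit <- stats::lm(pos[sel] ~ times[sel])
  co <- stats::coef(fit)
  structure(list(times = times[sel], interface = pos[sel],
                 slope = unname(co[2]), intercept = unname(co[1]),
                 rms_residual = sqrt(mean(stats::resid(fit)^2))),
            class = "wave_speed_fit")
}

#' @method print wave_speed_fit
#' @export
print.wave_speed_fit <- function(x, ...) {
  cat(sprintf("Front-tracking wave speed: v = %.6g (rms residual %.3g, %d points)\n",
              x$slope, x$rms_residual, length(x$times)))
  invisible(x)
}

#' L1 distance of biomass profiles to a reference snapshot
#'
#' Riemann-sum \eqn{L^1} distances \eqn{\int |M(t) - M_{ref}|\,dx} of every
#' snapshot to a chosen reference; a decreasing tail of this series is the
#' standard diagnostic of convergence to a travelling profile.
#'
#' @inheritParams estimate_wave_speed
#' @param ref_index index of the reference snapshot (default: the last).
#' @return A data frame with columns `t` and `l1`.
#' @export
l1_profile_difference <- function(snapshots, ref_index = length(snapshots)) {
  stopifnot(inherits(snapshots, "sim_snapshots"))
  ref <- snapshots[[ref_index]]
  vol <- ref$dx * if (is.null(ref$dy)) 1 else ref$dy
  l1 <- vapply(snapshots, function(s) {
    if (length(s$M) != length(ref$M)) stop("snapshots on mismatched grids")
    sum(abs(s$M - ref$M)) * vol
  }, numeric(1))
  data.frame(t = vapply(snapshots, function(s) s$t, numeric(1)), l1 = l1)
}

#' Embed a travelling-wave profile with a transverse perturbation
#'
#' Builds a 2D initial condition consisting of the 1D wave profile placed
#' with its front at `x_front`, plus a single transverse cosine mode of
#' index `n`: `M = M0(x - x_front) (1 + amplitude cos(2 pi n y / L))`, and
#' the substrate perturbed with the same bump shape (which vanishes at the
#' front and far behind it, as the mode ansatz requires). Fields are
#' clipped to their physical ranges.
#'
#' @param profile a [reconstruct_profile()] result.
#' @param n transverse mode index (`>= 1`).
#' @param amplitude relative perturbation amplitude.
#' @inheritParams initial_condition_1d
#' @param x_front front position in the domain (default `0.75 * H`).
#' @return A `field_state`.
#' @export
perturbed_tw_initial_condition <- function(profile, n, amplitude, cfg,
                                           x_front = 0.75 * cfg$H) {
  stopifnot(inherits(profile, "tw_profile"), inherits(cfg, "sim_config"))
  if (is.null(cfg$L)) stop("a 2D configuration (cfg$L) is required")
  if (n < 1) stop("mode index n must be >= 1")
  x <- cell_centres(cfg$H, cfg$dx)
  y <- cell_centres(cfg$L, cfg$dy)
  xi <- x - x_front
  Mfun <- stats::approxfun(profile$xi, profile$M, yleft = profile$M[1],
                           yright = 0)
  Sfun <- stats::approxfun(profile$xi, profile$S, yleft = profile$S[1],
                           yright = 1)
  M0 <- Mfun(xi); S0 <- Sfun(xi)
  M0[xi > 0] <- 0; S0[xi > 0] <- 1
  cosy <- cos(2 * pi * n * y / cfg$L)
  M <- outer(M0, 1 + amplitude * cosy)
  S <- matrix(S0, length(x), length(y)) + amplitude * outer(M0, cosy)
  if (max(M) >= 1) stop("perturbation amplitude too large: M reaches 1")
  S[S > 1] <- 1; S[S < 0] <- 0; M[M < 0] <- 0
  new_field_state(0, M, S, x, cfg$dx, y, cfg$dy)
}

#' Transverse Fourier mode amplitude
#'
#' Amplitude of the `cos(2 pi n y / L)` component of the biomass field,
#' `a_n(x) = (2/ny) sum_j M(x, y_j) cos(2 pi n y_j / L)`, reduced over `x`
#' by the maximum absolute value. Its decay in time diagnoses transverse
#' stability of a planar wave.
#'
#' @param state a 2D `field_state`.
#' @param n mode index (`>= 1`).
#' @return The scalar mode amplitude.
#' @export
transverse_mode_amplitude <- function(state, n) {
  stopifnot(inherits(state, "field_state"))
  if (is.null(state$ny)) stop("a 2D field state is required")
  cosy <- cos(2 * pi * n * state$y / (state$ny * state$dy))
  an <- as.numeric(state$M %*% cosy) * 2 / state$ny
  max(abs(an))
}
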