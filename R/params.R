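#' Dimensionless model parameters
#'
#' Bundle and validate the six dimensionless constants of the biofilm
#' PDE-ODE model. The biomass diffusivity is doubly degenerate,
#' \eqn{D(m) = \delta m^a / (1-m)^b}, vanishing as a power at \eqn{m = 0}
#' (sharp invasion front) and blowing up as \eqn{m \to 1} (density cap),
#' and the substrate uptake follows Monod kinetics
#' \eqn{f(s) = s/(\kappa + s)}.
#'
#' Defaults are the reference parameter set used throughout the numerical
#' study of the model: \eqn{\delta = 10^{-6}}, \eqn{a = b = 4},
#' \eqn{\kappa = 0.01}, \eqn{\gamma = 0.4}, \eqn{\lambda = 0.42}.
#'
#' @param delta motility (diffusion) coefficient, `> 0`.
#' @param a diffusion exponent controlling front steepness, `> 1`.
#' @param b diffusion exponent controlling the approach to the density cap,
#'   `> 1`.
#' @param kappa Monod half-saturation constant, in `(0, 1]`.
#' @param gamma maximum substrate consumption rate, in `(0, 1)`.
#' @param lam cell-loss (decay) rate, `> 0`. Values `>= 1` are admitted so
#'   that the non-existence regime can be probed, but no travelling wave
#'   exists there.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()
#' diffusion_D(0.5, p)
#' @export
model_params <- function(delta = 1e-6, a = 4, b = 4,
                         kappa = 0.01, gamma = 0.4, lam = 0.42) {
  chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid model parameter: ", what, call. = FALSE)
  for (nm in c("delta", "a", "b", "kappa", "gamma", "lam")) {
    v <- get(nm)
    chk(is.numeric(v) && length(v) == 1L && is.finite(v), paste(nm, "must be a finite number"))
  }
  chk(delta > 0, "delta must be > 0")
  chk(a > 1, "a must be > 1")
  chk(b > 1, "b must be > 1")
  chk(kappa > 0 && kappa <= 1, "kappa must be in (0, 1]")
  chk(gamma > 0 && gamma < 1, "gamma must be in (0, 1)")
  chk(lam > 0, "lam must be > 0")
  structure(list(delta = delta, a = a, b = b,
                 kappa = kappa, gamma = gamma, lam = lam),
            class = "model_params")
}

#' @method print model_params
#' @export
print.model_params <- function(x, ...) {
  cat("Biofilm model parameters (dimensionless):\n")
  cat(sprintf("  delta = %g  a = %g  b = %g\n", x$delta, x$a, x$b))
  cat(sprintf("  kappa = %g  gamma = %g  lambda = %g\n", x$kappa, x$gamma, x$lam))
  invisible(x)
}

# internal: flatten for the C++ kernels
pars_vec <- function(p) {
  stopifnot(inherits(p, "model_params"))
  c(p$delta, p$a, p$b, p$kappa, p$gamma, p$lam)
}
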