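# Shared fixtures. The default travelling-wave solve is used by several
# files; cache it so the bisection runs once per test session.
.tw_cache <- new.env(parent = emptyenv())

default_params <- function() model_params()

default_tw <- function() {
  if (is.null(.tw_cache$res))
    .tw_cache$res <- find_wave_speed(default_params())
  .tw_cache$res
}

# continuation test regime: moderate diffusivity so traversal times stay
# manageable (kappa = 1 leaves a high residual substrate level ~ 0.132)
continuation_params <- function(gamma = 0.3) {
  model_params(delta = 1, a = 2, b = 2, kappa = 1, gamma = gamma, lam = 0.3)
}

trapz <- function(x, y) sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))
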