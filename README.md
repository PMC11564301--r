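# biofilmTW

Travelling-wave machinery for a degenerate PDE–ODE model of cellulolytic
biofilm growth.

Cellulolytic biofilms grow *into* their substratum: colonies etch
crater-like depressions ("inverted colonies") whose rims advance at a
constant speed. The dimensionless model behind this package couples a
biomass density $M \in [0,1)$ with doubly degenerate diffusion to an
immobile substrate $S$:

$$
\partial_t M = \partial_x [D(M)\, \partial_x M] + (f(S) - \lambda) M,
\qquad
\partial_t S = -\gamma f(S) M,
$$

with $D(m) = \delta m^a/(1-m)^b$ ($a, b > 1$) and Monod uptake
$f(s) = s/(\kappa + s)$. Travelling-wave solutions $M(x - vt)$, $S(x - vt)$
are sharp-fronted pulses connecting the undisturbed state $(0, 1)$ ahead of
the wave to a depleted state $(0, s_{-\infty})$ behind it, where
$s_{-\infty}$ is the nontrivial root of $s + \lambda F(s) = 1$ with
$F(s) = 1 - s - \kappa \log s$.

The package provides, for people studying reaction–diffusion invasion
fronts with degenerate mobility (mathematical biologists, applied
analysts, and modellers of biofilm, fungal or tumour growth):

* **`model_core`** — the closed-form functionals ($D$, $f$, $F$, the
  nullcline $\ell$, the integral functional $\mathcal{G}$), log-space
  root-finding for the phase-plane landmarks (residual substrate levels
  down to $10^{-60}$ and beyond), and `existence_report()` evaluating both
  travelling-wave existence conditions plus the critical transverse strip
  width $2\pi/\sqrt{2f(1) - \lambda}$.
* **`find_wave_speed()`** — the wave profile and speed via adaptive RK4
  integration of the scaled phase-plane system and bisection on the orbit
  exit class (substrate line vs biomass axis), with profile
  reconstruction, the mass-balance (Rankine–Hugoniot) check
  $\omega(+\infty) = v(1-s_{-\infty})/(\lambda\gamma)$, front-exponent
  fitting ($M \sim |\xi|^{1/a}$), and a comparison-function envelope.
* **`simulate_pde()`** — a conservative finite-volume simulator of the
  full system on 1D intervals and 2D rectangles (trapezoidal rule, Picard
  iteration, arithmetic-mean face diffusivities), with front tracking,
  least-squares wave-speed estimation, $L^1$ convergence diagnostics, and
  transverse-perturbation experiments for planar-front stability.
* **`solve_connection()` / `sweep_gamma()`** — the heteroclinic two-point
  boundary-value problem by integrate-to-event shooting, and bifurcation
  sweeps of wave speed against the consumption rate $\gamma$, locating the
  non-existence threshold where $\mathcal{G}$ loses positivity.

## Worked example

```r
library(biofilmTW)

p <- model_params()   # delta = 1e-6, a = b = 4, kappa = 0.01,
                      # gamma = 0.4, lambda = 0.42
existence_report(p)
#> Travelling-wave existence report
#>   s_-inf = 1.0617e-60   (log s_-inf = -138.0952)
#>   s_M = 0.00724138   s_* = 2.43994e-19   s^* = 0.301667
#>   min G = 4.04e-07
#>   explicit parameter bound satisfied: TRUE
#>   G positive on (s_-inf, 1):          TRUE
#>   travelling wave predicted: TRUE (conditions_met)
#>   critical transverse strip width: 5.03026

res <- find_wave_speed(p)
res
#> Travelling wave: v = 0.0145428 (13 bisections)
#>   final orbit exit: substrate_line;  max M = 0.9026
#>   accumulated biomass omega_inf = 0.0865646
```

The wave advances at $v \approx 0.0145$ (distance per unit time in the
model's dimensionless units), its biomass peaks at $M \approx 0.90$, and
the total biomass carried by the wave, $\omega(+\infty) \approx 0.0866$,
equals $v(1 - s_{-\infty})/(\lambda\gamma)$ — the mass-balance identity
that ties the speed to the substrate consumed. The same wave emerges from
the PDE simulator started from an arbitrary colony seed:

```r
cfg <- sim_config(dx = 2^-10, t_end = 50, snapshot_times = seq(0, 50, by = 2))
snaps <- simulate_pde(cfg, p)
estimate_wave_speed(snaps, cfg)
#> Front-tracking wave speed: v = 0.0172119 (rms residual 0.000588, 15 points)
```

(coarse grids overestimate the speed of the sub-cell-sharp front; the
estimate converges towards the phase-plane value under grid refinement —
see the vignette).

A command-line front end wrapping these functions is installed at
`inst/cli/biofilmtw.R` (`analyze`, `tw`, `pde1d`, `continuation`,
`compare`).

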