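---
title: "Travelling waves of a degenerate biofilm model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Travelling waves of a degenerate biofilm model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmTW)
```

## The model

The package analyses the dimensionless PDE–ODE system

$$
\partial_t M = \partial_x\!\left[D(M)\,\partial_x M\right] + (f(S) - \lambda)\,M,
\qquad
\partial_t S = -\gamma\, f(S)\, M,
$$

describing a cellulolytic biofilm (volume fraction $M \in [0,1)$) degrading
an immobile substrate ($S \in [0,1]$). The two nonlinearities carry all of
the structure:

* the **doubly degenerate diffusivity** $D(m) = \delta\, m^a/(1-m)^b$ with
  $a, b > 1$ vanishes at $m = 0$, which produces a *sharp*, finite
  invasion front (unlike Fisher-type fronts, which have exponential
  tails), and blows up at $m = 1$, which caps the biomass density below
  its physical packing limit;
* the **Monod uptake** $f(s) = s/(\kappa + s)$ saturates, so growth is
  substrate-limited only below the half-saturation level $\kappa$.

Because the substrate does not move, the invasion takes the form of a
travelling *pulse*: a biomass wave of fixed shape moving at constant speed
$v$, consuming substrate down to a residual level $s_{-\infty}$ behind it.
In the wave coordinate $\xi = x - vt$ the system reduces to a planar
vector field whose heteroclinic connection between $(0, s_{-\infty})$ and
$(0, 1)$ *is* the wave.

### Closed-form functionals

All existence machinery rests on three functions with Monod closed forms
(used throughout; adaptive quadrature is the fallback for a user-supplied
uptake function):

* $F(s) = \int_s^1 d\rho/f(\rho) = 1 - s - \kappa\log s$, the accumulated
  inverse uptake rate;
* the biomass nullcline $\ell(s) = \gamma^{-1}[(1-s) - \lambda F(s)]$,
  whose graph the orbit must cross at its biomass maximum;
* $\mathcal{G}(s) = \int_s^1 (\rho + \lambda F(\rho) - (1-\gamma))\,
  d\rho/f(\rho) = \kappa(1-s) + \tfrac{1-s^2}{2} + \tfrac{\lambda}{2}F^2(s)
  - (1-\gamma)F(s)$.

Two conditions govern existence: the explicit parameter bound
$\gamma + \lambda + \kappa\lambda\,(1 - \log(\kappa\lambda/(1-\lambda)))
\le 1$ (sufficient, together with the next, but not necessary), and strict
positivity of $\mathcal{G}$ on $(s_{-\infty}, 1)$ (necessary). Both are
evaluated by `existence_report()`.

### Where the minimum of $\mathcal{G}$ really sits

$\mathcal{G}'$ changes sign exactly at the roots of
$g(s) = s + \lambda F(s) = 1 - \gamma$, so the interior minimum of
$\mathcal{G}$ is at the *lower* root $s_*$. For small $\kappa$ this root is
astronomically small — at $\gamma = 0.4$, $\kappa = 0.01$ it ranges from
about $10^{-19}$ ($\lambda = 0.42$) down to $10^{-57}$ ($\lambda = 0.26$) —
far below anything a grid search in linear space can see. The package
therefore evaluates the landmark roots ($s_{-\infty}$, $s_*$) in
**log-space** and always includes $s_*$ as a candidate when minimising
$\mathcal{G}$, in addition to a 2048-point log-spaced grid with local
refinement. This choice is load-bearing: a minimum search truncated near
$s \approx 10^{-5}$ misclassifies the integral condition over a sizeable
$\lambda$ range, and the exactly-evaluated boundary is the one that
coincides with where the wave solvers stop finding waves.

## The wave solver (phase-plane bisection)

In the scaled coordinate $\tau$ (with $d\tau = d\xi / D(M)$) the wave
system becomes regular, and the solver integrates its *negated* field

$$
\frac{dM}{d\tau} = -v[\ell(S) - M], \qquad
\frac{dS}{d\tau} = -\frac{\gamma}{v} f(S)\, M\, D(M)
$$

forward from the launch point $(\varepsilon, 1)$ with $\varepsilon =
10^{-3}$, i.e. from just behind the sharp front. Orbits split into two
classes: too-fast speeds deplete the substrate to $s_{-\infty}$ while
biomass remains, too-slow speeds drop the biomass to zero first. The wave
speed is the separating value, found by geometric bracket expansion and
bisection to a relative tolerance of $10^{-4}$.

Numerical choices that matter:

* **Integrator.** Embedded RK4 with step-doubling error control
  (relative tolerance $10^{-8}$) and a hard cap of $10^{-3}$ on the
  per-step change of either component. Error control is **component-wise
  relative**: the substrate coordinate decays over as many as sixty
  decades towards $s_{-\infty}$, and only a relative measure keeps it
  meaningful there.
* **Exit thresholds.** The biomass axis counts as hit at
  $M \le 10^{-9}$. The substrate line counts as hit at
  $S \le s_{-\infty}(1 + 10^{-6})$, with a hard floor at $10^{-300}$
  (the edge of the double range). The floor intentionally follows
  $s_{-\infty}$ itself even when that is $\sim 10^{-60}$: the two exit
  classes only separate once $S$ has descended to the residual scale, and
  truncating higher (say at $10^{-12}$) silently misclassifies slow
  orbits as fast ones and drags the bisection far off the true speed.
* **Degenerate cases.** An orbit reaching $M \ge 1 - 10^{-9}$ signals a
  step-size failure (the continuous orbit cannot cross $m = 1$); it is
  flagged and conservatively classified with the fast branch, which is
  the only regime where it occurs. Orbits hitting the $\tau$ cap are
  classified with the slow branch, with a warning, so the bisection stays
  well defined.
* **Profile reconstruction.** $\xi$ is recovered by trapezoidal
  accumulation of $d\xi = D(M)\,d\tau$ with $\xi = 0$ at the launch point
  (the front), and the accumulated biomass $\omega$ from its first
  integral $\omega = (v/\gamma)[(1-s_{-\infty})/\lambda - F(S)]$, so the
  mass-balance limit $\omega(+\infty) = v(1 - s_{-\infty})/(\lambda\gamma)$
  is available in closed form and the quadrature of $\int M\,d\xi$ can be
  tested against it.
* **Front asymptotics.** Behind the front the balance
  $\delta M^{a-1} M' \sim -v$ integrates to
  $M \sim (a v |\xi| / \delta)^{1/a}$; `front_exponent_fit()` fits the
  exponent on the window $M \in [10^{-2}, 5\times 10^{-2}]$, chosen so the
  launch offset $\varepsilon$ contributes negligibly at the lower end and
  $(1-M)^b \approx 1$ at the upper end.

## The finite-volume simulator

The full system is solved on uniform 1D/2D grids with a two-point
flux-approximation finite-volume scheme, zero-flux boundaries, and the
trapezoidal (Crank–Nicolson) rule in time. Face diffusivities are
**arithmetic means** of the cell-centred $D(M)$ — a harmonic mean would
annihilate the flux at the degenerate front, freezing it. The coupled
nonlinear update is solved per step by Picard iteration with lagged
diffusivity and lagged reaction factors; the biomass sub-step is then a
tridiagonal (1D) or sparse (2D) linear solve, and the substrate update is
pointwise. The iteration stops at a max-norm increment below $10^{-9}$
(cap 200; failure aborts with advice to reduce `dt`). The flux form
telescopes, so with reactions disabled total biomass is conserved to
round-off — a property the tests assert at $10^{-12}$.

The default discretisation follows the reference scaling $\Delta x =
2^{-N}$, $\Delta t = 10^{-2}(2^9 \Delta x)^2$, with the quartic colony
seed ($d = 5/127$, $h = 0.1$) and $S \equiv 1$. The front is tracked as
the largest cell centre with $M > 10^{-2}$ and the speed fitted by
ordinary least squares over the trailing 60% of snapshots, skipping any
snapshot before the interface has moved at least five cells.

**Problem sizes.** The wave front is *sub-cell-width sharp* ($M$ climbs to
0.9 within $|\xi| \sim 10^{-5}$ at the defaults), so coarse grids
systematically overestimate the speed, and the overshoot shrinks by a
factor of roughly 0.6 per refinement level. The package's end-to-end
checks therefore run the grid-convergence sequence $N \in \{10, 11, 12\}$
to $t = 50$ and require the $N = 12$ speed to sit within 10% of the
phase-plane speed; $N = 12$ is the coarsest level that reaches that band,
and it completes in minutes on one CPU. Finer levels (the reference
discretisation at $N = 14$) continue the same convergence trend but are overnight-scale
runs, not part of the default suite.

**What the seeded initial conditions do and do not emulate.** The quartic
colony is deliberately unrelated to the wave profile: convergence of the
simulation onto a translating profile is then evidence of the wave's
stability, not an artefact of initialisation. The seeds are smooth,
noise-free and single-colony; real inocula are rough and multi-colony, so
passing tests demonstrate attraction of the travelling wave within this
idealised class, not robustness to arbitrary field data.

For transverse stability, `perturbed_tw_initial_condition()` embeds the
1D profile in a strip of width $L$ and modulates it with a single cosine
mode whose shape vanishes at the front and far behind it (the biomass
profile itself is used as the bump). Linear theory guarantees decay of
all transverse modes when $L < 2\pi/\sqrt{2 f(1) - \lambda}$; the package
probes this by nonlinear simulation, monitoring the discrete cosine-mode
amplitude, rather than by evolving the linearised mode systems.

## The heteroclinic boundary-value solver

The connection can also be computed as a two-point boundary-value problem
on $\tau \in [0, 1]$: the field above multiplied by an unknown traversal
time $T$, launched on the centre-unstable manifold at $(\varepsilon_0,
s_{\varepsilon_0})$ — with $s_{\varepsilon_0}$ the smallest root of
$\ell(s) = \varepsilon_0$, since the manifold is approximated to order
$M^{1+a}$ by the nullcline — and required to land at $(\varepsilon_1, 1)$.

The design here was genuinely open, and the obvious formulation fails in
instructive ways:

* a damped Newton iteration on the raw $(v, T)$ system has a **spurious
  residual-zero family** as $vT \to 0$ (the biomass never leaves the
  launch offset while the substrate equilibrates through the
  $\gamma/v$-scaled equation), and its fixed-interval residual is
  one-sided in $T$ because overshooting $S = 1$ leaves the phase strip;
* near the rest state the biomass mobility $M D(M) = O(M^{1+a})$ makes
  the orbit *crawl*: traversal times are $10^5$–$10^7$ even at
  $\delta = 1$, so $T$ cannot be guessed, only measured;
* the forward orbits order **inversely** with $v$ (large speeds shed
  their biomass early), the mirror image of the backward family used by
  the bisection solver;
* for $v$ above the connection speed the forward orbit relaxes onto the
  nullcline and slides into $(0, 1)$ along it, so the terminal mismatch
  saturates at the endpoint-truncation scale
  $\varepsilon_1/|\ell'(1)|$ and no shooting method can reduce it
  further, even though $v$ itself remains sharply determined.

`solve_connection()` therefore solves the system by elimination: an
integrate-to-event formulation stops each orbit when the biomass falls
back through $\varepsilon_1$ (the field is perfectly regular slightly
beyond $s = 1$, so orbits may legitimately overshoot the substrate
boundary), classifies the speed by whether the substrate has passed 1 at
that crossing, and bisects on $v$; $T$ is the measured traversal time and
the reported residual is the terminal substrate mismatch. The
`shooting_residual()` of the returned $(v, T)$ pair is kept as an
interface and cross-check. The convergence tolerance `newton_tol`
defaults to $10^{-2}$, deliberately above the truncation scale
$\sim 10^{-3}$; tightening it below that scale would reject exact
connections. Sweeps in $\gamma$ (`sweep_gamma()`) use a secant predictor
for the speed and stop at the first failure, which brackets the
non-existence threshold where $\mathcal{G}$ loses positivity.

The continuation test regime uses $\delta = 1$ (with $a = b = 2$,
$\kappa = 1$, $\lambda = 0.3$): the wave speed scales exactly as
$\sqrt{\delta}$ — a rescaling invariance of the wave system that the
tests verify across six orders of magnitude — so nothing is lost, and the
traversal times stay manageable.

## Worked example

```{r example, eval = FALSE}
p <- model_params()          # delta 1e-6, a = b = 4, kappa 0.01,
                             # gamma 0.4, lambda 0.42
existence_report(p)          # landmarks + both existence conditions
res <- find_wave_speed(p)    # v ~ 0.0145, profile, orbit, brackets
front_exponent_fit(res$profile, p)   # exponent ~ 1/a = 0.25
```

## Known limitations

* The existence theory is implemented for Monod uptake in closed form;
  the quadrature fallback for general $f$ covers the functionals but the
  landmark root-finding assumes the Monod $g$-geometry.
* Single shooting caps the achievable terminal residual of the
  boundary-value solver at the $\varepsilon_1$-truncation scale (see
  above); a collocation discretisation with a phase condition would be
  needed to do better.
* Coarse-grid finite-volume speeds carry a systematic positive bias of
  order 10–20% at $N \le 11$ because the degenerate front is sub-cell
  sharp; conclusions about absolute speeds should use the phase-plane
  solver, with the PDE runs serving as independent confirmation of the
  wave's existence, stability and approximate speed.
* Near the non-existence thresholds (small $\gamma$, small $\lambda$)
  traversal times and profile widths blow up and all solvers slow down;
  the bisection reports bracket failure rather than attempting to
  resolve waves it cannot.
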