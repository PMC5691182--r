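---
title: "Continuing dynamics through finite-time blow-up: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuing dynamics through finite-time blow-up: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(blowthrough)
```

This vignette is the package's own account of the science and the numerical
design behind it: what is assumed, what is tuned, why the defaults are what
they are, and where the method's validity ends.

## The continuation idea

A scalar ODE dx/dt = f(x) blows up self-similarly when, near the collapse
time t\*, the right-hand side is dominated by a power, f(x) ~ x^p with
p > 1, so that x(t) ~ (t\* − t)^{1/(1−p)}. The singular change of variable

y = x^{1−p}

maps the approach to infinity onto an approach to zero, and the chain rule
turns dx/dt = f(x) into a "good" equation for y that is *regular at the
crossing*: for the pure power f = x^p it is exactly dy/dt = 1 − p, and for
full right-hand sides with lower-order ("offending") terms the transformed
equation picks up regular corrections (for f = 2x + x², y = 1/x obeys
dy/dt = −2y − 1; for the quadratic integrate-and-fire model f = I + v²,
y = 1/v obeys dy/dt = −1 − I y²). Zero is crossed, the inverse transform is
applied, and the original equation resumes on the far side of infinity.

The protocol implemented by `integrate_crossing()` is therefore:

1. integrate the original equation, monitoring the diverging component;
2. at magnitude `switch_high`, fit log |dx/dt| against log |x| over the
   trailing samples; accept the blow-up as asymptotically self-similar only
   if the fit is convincing, otherwise halt rather than guess;
3. switch by continuity to the transformed equation and run it until zero
   is *safely* crossed (|y| = `switch_low` on the far side);
4. invert the transform and march the original equation on.

### Assumptions

* The divergence is asymptotically a **power law** with p > 1. Exponential
  growth (p = 1) reaches any threshold but never blows up in finite time;
  the detector rejects it (the fitted power must exceed 1.1).
* A **single designated component** diverges (`blowing` in
  `ode_problem()`). When one component of a system blows up while the rest
  stay regular (quartic integrate-and-fire), `transform_subsystem()`
  transforms that component only. When two components blow up
  simultaneously (quadratic 2D integrate-and-fire), the state is first
  rewritten in polar coordinates (`polar_decompose()`), after which the
  radius alone diverges. General norm-based monitoring of
  high-dimensional blow-up is out of scope.
* The right-hand side is evaluable at any finite state, and — if a
  multivalued reentry branch is taken — at complex states too.

### Tunable parameters

All live in `switch_policy()`:

| parameter | default | meaning and rationale |
|---|---|---|
| `switch_high` | 100 | magnitude (dimensionless state units) of the diverging component that triggers the switch. Large enough that the dominant power typically wins by two orders of magnitude; small enough that the original equation is still far from overflow. |
| `switch_low` | 0.01 | distance past zero the good variable must travel before reverting ("safely crossed"). How long to wait is genuinely open; 0.01 pairs with `switch_high` = 100 so that for p = 2 the state re-enters at the mirror-image magnitude. |
| `exponent_window` | 50 | trailing samples offered to the power fit. The fit itself restricts to the trailing run with \|x\| ≥ `switch_high`/3, where subdominant terms contribute at the percent level or less. |
| `min_fit_r2` | 0.999 | acceptance R² for the log-log fit. Pure powers give 1 to machine precision; asymptotically self-similar models give ≥ 0.999 over the restricted window; non-power growth fails clearly. |
| `rtol`, `atol` | 1e-8 | tolerances of the adaptive solver in both regimes. |

Fitted powers within 0.05 of an integer are snapped to it: the worked
models all have integer powers, and snapping yields *exact* good equations
(`y = 1/x` rather than `y = x^{-0.98}`), which in turn makes the reentry
branch well defined.

### Numerical choices

* **Time stepping** is delegated to `deSolve::lsodar` — adaptive, with
  dense output and root finding. Roots arm the regime switches; after a
  reentry at magnitude `switch_high` the blow-up root is re-armed only once
  the magnitude has receded below half the threshold (hysteresis against
  immediate retriggering).
* **The good equation is built by the exact chain rule on the full
  right-hand side**, not only the dominant term, so asymptotically
  self-similar models are integrated exactly in the transformed variable.
  Evaluating it near y = 0 inverts the transform first; the inverse image
  is magnitude-clipped at 10^(250/p) so that dominant-balance ratios are
  exact to machine precision while no intermediate overflows double
  precision.
* **The crossing time t\*** is reported from the linear zero crossing of
  the good variable's dense output, not from extrapolating the diverging
  variable. The solver is deliberately *not* stopped at y = 0: for coupled
  systems the crossing instant is a delicate point of the companion
  equations (the polar angle passes through π/2 exactly as the radius
  transform crosses zero), and restarting there amplifies error. The
  passage is instead resolved on a fine output grid sized by the entry
  speed of the good variable.
* **Branch policy.** For odd p the inverse of y = x^{1−p} is multivalued
  past the crossing; the solution may re-enter from +i∞ or −i∞. This is
  the phase-loss ambiguity, and it is exposed as `branch =
  "plus_i"`/`"minus_i"` (default `plus_i`; `real_continuation` errors).
  Post-crossing states are then complex and the original equation is
  integrated as a real system of twice the dimension.
* **Degenerate inputs.** An initial state exactly at a fixed point never
  triggers a detection; bounded dynamics produce a single segment and an
  empty event table.
* **Guard rails.** If the good equation itself approaches blow-up before
  recrossing (possible for the quadratic IF good equation at large |y|),
  or a non-transformed component deviates by more than `switch_high`
  during a crossing, integration stops with an explicit error; nested
  transforms are not attempted. `check_bounded_companions()` additionally
  diagnoses, after the fact, whether the companions' dynamics were
  integrable through the crossing (|du/dt| ~ |y|^{−q} with q < 1): applying
  a single-component transform to the 2D quadratic model — where both
  components blow up — is flagged by this diagnostic rather than silently
  accepted.

## The PDE solver

For the focusing equation w_t = w_xx − (2/w)w_x² + w + r w² (the level-set
view w = 1/(u − r) of the linear field u_t = u_xx − u), infinity is touched
at a point and then *crossed for an extended time* along two separating
space-time curves. The transformation v = 1/w, whose good equation is the
linear v_t = v_xx − v − r, therefore cannot be applied globally — v itself
vanishes far from the tip — and is confined to **singular buffer regions**:

* nodes with |w| ≥ `W_max` (default 1e4), expanded by `margin` (default 5)
  nodes on each side, form a buffer solved in v;
* before the first buffer is declared, the growth of max|w| must pass an
  on-the-fly power-law check (fit of d(max w)/dt against max w on log-log
  scale, R² ≥ `exponent_check` = 0.99, fitted power above 1), and the
  detected time-scaling exponent alpha = 1/(1 − p) is reported;
* after the crossing, the buffer splits around the two separating zero
  crossings of v once an interior span of at least 2·`margin` nodes has
  receded below `W_max` (margin-based hysteresis prevents partition
  flapping), giving the 1 → 3 → 5 region history;
* the partition is re-evaluated every `era_len` = 10 steps (a
  "computational era") — and immediately whenever a regular node crosses
  `W_max`, because the focusing growth (local doubling time ~ 1/(r w))
  would otherwise outrun the implicit solver within a single era.

**Gluing.** Each step, the two nodes flanking every internal interface are
advanced by explicit forward Euler in their own representation (with the
neighbor converted nodewise through v·w = 1); those values then serve as
Dirichlet data for a backward-Euler solve of each region's interior
(Newton iteration with an analytic tridiagonal Jacobian for the nonlinear
regions, a single tridiagonal solve for the linear buffers; the Thomas
solver is the package's only compiled code). The explicit interface step
requires dt ≤ h²/4, enforced at configuration time. Each region stores
only its own variable — near-infinite values of w are never materialized.

**Discretization of the singular term.** The combination
w_xx − (2/w)w_x² equals −w² (1/w)_xx identically, and the package
discretizes it in that gradient-free form (still second-order central
differences, mirrored ghost nodes at the Neumann ends). The difference
matters: discretizing the two terms separately leaves a truncation error
proportional to fourth derivatives of w, which grow without bound as the
crossing front steepens — relative errors of several percent persist a
handful of nodes from the locus at N = 401 no matter how small dt is. In
the gradient-free form the truncation error is proportional to
(1/w)_xxxx, i.e. to the *smooth* reciprocal field, and the solution stays
within one percent of the closed-form reference right up to `margin`
nodes from the crossing locus.

**Problem sizes.** The reference configuration (used by the acceptance
script and the headline tests) is N = 401 nodes on [0, π], dt = 1e-5, run
to just past the first touch; unit tests exercise the full 1 → 3 → 5
history at N = 101 with proportionally larger dt and a lower `W_max` so
the whole suite stays fast. Oracle-equivalence checks run to t = 0.4: with
the catalog initial data the two crossings reach the Neumann boundaries
near t ≈ 0.45, a topology the solver deliberately refuses (see
limitations).

## Compactification and complexification

The compactification maps place infinity on the same footing as every
other point of an orbit: power-law blow-up maps to a unit circle via
X = ((t\*−t)^a − x)/((t\*−t)^a + x), Y = 2/((t\*−t)^a + x), with exact
variants for exponential dynamics (tanh/sech identity) and for the
asymptotically self-similar model (replacing t\* − t by its exponential
surrogate). These identities hold exactly on orbits normalized to unit
self-similar prefactor ((t\*−t)^a·x = 1); the maps are exercised on such
orbits, and for numerical trajectories t\* is taken from the integrator's
crossing event, never from closed forms. Self-similar PDE profiles
u = f(ξ)/(t\*−t)^r with the profile normalized to |f| ≤ 1 (and f ≥ 0, the
bell-shaped case the construction addresses) map onto a unit sphere;
θ is reported in (−π, π] by the atan2 convention. The Riemann-sphere map
is the standard inverse stereographic projection; all points at complex
infinity are identified with the north pole, rationalizing the vanishing
transit time between infinities, which the contour integral
T = ∮ dz/z^p makes quantitative (T·R^{p−1} constant).

Complexifying dz/dt = z² turns real collapse into closed circular orbits
x² + (y − R)² = R² conserving E = (x² + y²)/y; the real dynamics is the
flat-circle limit. The complexified level-set PDE (real/imaginary pair for
w = a + ib) is integrated by Fourier-cosine spectral collocation rather
than the finite-difference stencil of the buffered solver: the fields are
even, π-periodic and analytic, so spectral differentiation makes the
spatial error negligible against the time-integration tolerance — a
second-order stencil would bury the comparison against the analytic
reconstruction oracle (w = 1/v with the linear complex v solved exactly by
eigenfunction expansion) under amplified truncation error near the
level-set crossing, where the reconstruction's sensitivity to the good
field scales like 1/d². The imaginary seed amplitude for the demonstration
runs, d = 0.05 constant in space, is the package's choice (nothing pins it
physically); it is an explicit argument everywhere.

## MN-dynamics (co-exploding frame)

Rescaling u = A(τ) f(ξ), ξ = x/L(τ), with the gauge τ_t = A^{s−1}, renders
a self-similar collapse stationary provided the spatial operator (~L^{−a})
and the nonlinearity (~A^{s−1}) scale together, forcing A ~ L^{−a/(s−1)}
and the exponents A ~ (t\*−t)^{1/(1−s)}, L ~ (t\*−t)^{1/a}. The package
implements this scaling calculus (`predict_scalings`) and its empirical
verification (`fit_amplitude_width`): A is the tip magnitude max|w| and L
the full width at half maximum of |w| — the operational definition of the
width is the package's own choice; FWHM is measured by linear interpolation
of the reciprocal magnitude profile, which is finite through the crossing. The
full co-exploding-frame integration (solving the stationary profile
equation) is deliberately not implemented: the frame is used here as the
scaling rationale for choosing the transformation, not as a solver.

## The fixture generator

`make_fixture()` samples closed-form blow-up trajectories (states and
derivatives) on a user grid, optionally degraded by multiplicative
lognormal noise with an explicit seed; noise is applied independently to
states and derivatives, emulating measurement error on both channels of
the estimator's input. It emulates exactly one thing: a diverging time
series whose growth law is known. It does not emulate solver error
correlation, non-stationary noise, or model misspecification — passing
estimator tests on fixtures shows that the log-log fit recovers known
powers at realistic noise (1%), not that detection is robust on arbitrary
real data. Trajectory grids that touch or straddle the collapse time are
refused; near-t\* evaluations use expm1-style forms to avoid catastrophic
cancellation.

## Known limitations

* Fractional blow-up powers are rejected in the model catalog (uniqueness
  of the continuation is not guaranteed); the engine itself snaps only
  near-integer fits and will otherwise use the fitted power with the
  sign-preserving real branch, which is a convention, not a theorem.
* The PDE solver supports the generic 1D scenario only: one touch opening
  into two crossings (at most 5 regions). Buffers reaching the domain
  boundary, incomplete blow-up over intervals, transient touch-without-
  crossing, and higher dimensions all stop with explicit errors.
* The buffered scheme is first order in time (backward/forward Euler, as
  designed); halving h and dt halves the error. The reported first-touch
  time is accurate to the era cadence.
* Post-crossing reentry for coupled systems (polar quadratic IF) passes
  through a mildly repelling manifold; the continuation is numerically
  well behaved but inherits sensitivity analogous to the scalar phase
  loss.
* The complexified PDE requires a²+b² > 0; real data that collapse make
  it vanish at the crossing, and the solver stops with a
  division-singular error there — complexification regularizes only
  genuinely complex data.
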