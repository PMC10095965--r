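---
title: "Mechanics of shoot gravitropism with a growing elastic rod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of shoot gravitropism with a growing elastic rod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravibend)
```

## The model

A gravistimulated shoot laid horizontally bends upward over a couple of
hours. `gravibend` treats the shoot centerline as a growing planar elastic
rod. Three ingredients interact:

1. **Elasticity.** The centerline is discretized into vertices joined by
   stretching springs (stiffness `ks`, natural lengths `a_i`) with angular
   springs at interior vertices (discrete bending stiffness
   `kb_i = B / abar_i`, where `abar_i` is the Voronoi length built from the
   natural lengths and `B` the bending modulus). Gravity acts through
   lumped vertex masses `m_i = rho * abar_i` (half segments at the two
   ends). At every instant the configuration is the mechanical equilibrium
   of these three potentials with the base clamped (first two vertices
   frozen, fixing position and tangent) and the apex force- and
   moment-free. The rod is kept practically inextensible (equilibrium bond
   strains stay below 1e-3 with the default `ks`).

2. **Growth.** Natural lengths of all bonds whose natural-arc midpoint lies
   within `Lgz` of the apical end elongate at the uniform relative rate
   `v / Lgz`; the zone advects with the tip as the shoot grows. The clamped
   basal bond never grows: growth between two frozen vertices cannot be
   expressed and would only accumulate spurious stretching energy (the
   effect of this exclusion on the extension ratio is below 0.2%).

3. **Gravi-proprioception.** In the growing zone the intrinsic
   (stress-free) curvature of each interior vertex evolves as

   `dkappa0/dt = beta * sigma * cos(theta) - gamma * kappa`,

   a gravitropic term proportional to the sine of the angle from the
   vertical (maximal for a horizontal segment, vanishing upright) opposed
   by proprioceptive straightening proportional to the current realized
   curvature. `beta` (1/(mm min)) and `gamma` (1/min) are the gravitropic
   and proprioceptive sensitivities; `sigma` picks the upward-bending
   curvature sign for the rod's pointing direction. A flag
   (`proprio_on_intrinsic`) lets proprioception read `kappa0` instead of
   the realized `kappa`; the default is the realized curvature, since
   proprioception is a response to the organ's actual shape.

The simulation loop (`simulate_shoot()`) alternates: record the
equilibrium, grow, update the intrinsic curvature, re-equilibrate, with
`dt = 1` min matching a one-frame-per-minute acquisition. Halving `dt`
changes the final maximum curvature by less than 2% (shipped as a test).

Three length scales organize the behaviour: the sensitivity length
`ls = gamma / beta` (where gravitropic bending and proprioceptive
straightening balance), the growing-zone length `Lgz`, and the
elasto-gravity length `Lg = (B / (rho g))^(1/3)` over which elasticity
resists sagging. The two dimensionless control parameters are
`S = Lgz / ls` (growth sensitivity) and `Gt = Lg / Lgz`
(growth-elasto-gravity). Only the products `rho * g` and the ratios above
matter; the package works in mm and min with the force unit fixed by
`B = 1`.

## Numerical choices

**Equilibration.** The textbook relaxation is overdamped gradient descent
`x <- x + mu * F * dtau` (available as `method = "gd"`). At the stated
stiffness contrast the elastic Hessian's condition number is ~1e8, and
first-order schemes need ~5e4 iterations per growth step even warm-started.
The default is therefore a damped Newton method: the Hessian couples
vertices at most two apart, so in interleaved DOF ordering it is banded
(half-bandwidth 5) and one Cholesky factorization plus a solve is O(N);
Levenberg regularization and an Armijo line search guard the
far-from-minimum regime. Warm-started growth steps converge in ~10
iterations; a 140-min run of a 41-vertex shoot takes about 1.5 s.

**Displacement attribution.** The decomposition of motion into stretching,
bending and gravity contributions integrates `mu * F_c * dtau` along the
relaxation path — at equilibrium the components balance to zero, so only a
path integral can attribute motion. Every scheme offered here takes steps
that are a *linear operator applied to the total force* (a scalar for
gradient descent and FIRE, `(H + lambda I)^-1` for Newton), so applying the
same operator to each component yields per-component displacements that sum
to the total step exactly; the additivity residual in practice is ~1e-15.
The absolute magnitudes of the attributed displacements depend on the
relaxation path (they differ slightly between `"gd"` and `"newton"`), but
the sign structure and relative comparisons — which is what the biology
rests on — do not.

**Force summaries.** The stretching and bending forces of interest are the
*active* out-of-balance forces present at the start of each relaxation:
the force injected by the growth increment (the growth-curvature-induced
bending, GCB) and by the gravi-proprioceptive curvature increment (the
gravi-proprioceptive response, GPR). `F_s_max` and `F_b_max` are maxima of
their signed projections onto the local bending direction. The projection
matters: the raw stretching force also contains a purely axial stress jump
`ks * da` at the discrete growth-zone boundary, an artifact of zone
quantization that is independent of the bending state (and hence identical
across genotypes); only the bending-directed part carries the biology. With
the default synthetic cohorts, the mutant-like model's maxima come out
roughly half the wild-type-like ones for both forces.

**Clamp discretization.** The discrete clamp freezes the first bond; its
effective continuum root sits at the middle of that bond, so cantilever
benchmarks compare against `rho g (L - a/2)^4 / (8 B)`. With 41 vertices
this closed form is reproduced to 0.1%.

## Centerline analysis

Digitized centerlines (about 20 points per frame, a typical manual
digitization density; positional noise ~0.1 mm) are fitted per frame with
cubic splines against the chord-length parameter and reparameterized by arc
length (trapezoid quadrature refined to 1e-5 relative). The default is a
penalized spline of fixed effective dimension `df = min(5, n - 2)`:
calibration on a noisy-circle oracle (n = 20, sigma = 0.05-0.1 mm) showed
that fixed moderate stiffness beats GCV-selected penalties on such short
samples, cutting the noise-induced positive bias of the maximum-curvature
statistic from ~40% to ~7%. Signed curvature
`kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)` is evaluated on a 0.5-mm
arc-length grid and smoothed with a 7-sample moving average; one window at
each end is excluded from maxima (spline edge artifacts). Noise-free inputs
(e.g. model output) should be analyzed with `smoothing = 0`
(interpolation).

The morphospace of a bending event is the pair (extension ratio
`L_end / L_start`, maximum |curvature| at 140 min). A strain variant
`(L_end - L_start) / L_start` is available behind a flag; cohort
comparisons are invariant to the choice.

## Fitting and identifiability

`grid_search()` scans an (S, Gt) grid — by default one decade around
(1, 1), 10 log-spaced nodes per axis — simulating a shoot at each node and
measuring its morphospace point through the *same* analysis pipeline as the
data (noise-free sampling at the data's digitization density, so spline
attenuation cancels in the comparison). The deviation is the scale-free
quadratic `D = ((kmax_m - kmax_d)/kmax_d)^2 + ((eps_m - eps_d)/eps_d)^2`
with configurable weights; ties break to the smallest S, then Gt. S is
realized through `beta = S * gamma / Lgz` at a fixed representative
`gamma`, and `Gt` through the linear density `rho`; the growing zone is
fixed to the initial length.

A caveat the tests make explicit: in the regime where elasticity easily
carries the shoot's weight (`Gt` of order 1 and above), the maximum
curvature at 140 min moves by only ~1-2% per grid cell along the `Gt` axis
while digitization noise moves the measured maximum curvature by ~5-10%.
`S` is then recovered reliably (it shifts the maximum curvature by ~30% per
cell), but `Gt` is effectively unidentified by this two-number morphospace.
This is a genuine limitation of morphospace-level fitting, not of the
implementation; resolving `Gt` would require fitting the spatio-temporal
curvature field rather than two summary numbers, or data in a
strongly sagging regime.

## The synthetic world

No experimental dataset ships with the package. `make_cohorts()` generates
a realistic two-genotype experiment: 16 wild-type-like and 15 mutant-like
shoots, initial
lengths drawn around 45 mm (truncated to the 40-80 mm range), base angles
near horizontal (5 degrees jitter), frames once per minute for 140 min,
20 digitized points per frame with isotropic Gaussian noise of 0.1 mm and
no temporal correlation. Wild-type-like sensitivities default to
`beta = 1e-3` /(mm min) and `gamma = 0.02` /min (sensitivity length 20 mm,
S = 2 for a 40-mm shoot — order-one, as posture control requires), growth
`v = 0.02` mm/min (extension ratio ~1.07 over 140 min), and `Gt = 1`. The
mutant-like cohort differs *only* in a halved `beta` — gravitropic
sensitivity — with identical proprioception and growth; that is the
package's encoding of a gravitropic-signalling mutant, and it reproduces
the qualitative contrast: lower maximum curvature, indistinguishable
extension ratio, weaker internal stretching and bending forces.

What a green test on this world does establish: the mechanics solves its
oracles (cantilever, force gradients, fixed point of the curvature law),
the analysis pipeline round-trips the simulator, and cohort-level sign
structure matches. What it cannot establish: agreement with any real
shoot's absolute parameter values, images-to-points digitization effects
beyond iid noise, 3-D torsion/twist, lignification-driven stiffening or
gravisensing delays (all outside the model by design).

## Differential cell growth

Treating the shoot as a solid rod of radius `R` (default 0.5 mm), the two
flanks of a segment with natural length `a` and intrinsic curvature
`kappa0` have natural lengths `a (1 +/- R kappa0)`; their relative
elongation rates `Edot = d ln L / dt` give
`DCG = Edot_in - Edot_out` — negative while the outer flank outgrows the
inner one (upward bending), positive when the shoot straightens. A
normalized variant (divided by the mean absolute flank rate) is available
behind a flag. When `R * dkappa0/dt` exceeds the relative growth rate
`v / Lgz`, the inner flank's rate turns negative while the outer stays
positive — the model predicts actual shrinkage of inner-flank tissue, a
testable cell-level statement. The default synthetic world sits almost
exactly on this threshold near the tip (`R beta cos(theta)` ~ 4.5e-4 /min
versus `v/Lgz` = 5e-4 /min), so tip shrinkage there is marginal; a slightly
thicker shoot or faster gravi-proprioceptive response tips it over.

## Known limitations

- Planar rods only; no torsion, shear, or out-of-plane buckling.
- No rigidity growth (lignification) or gravisensing delay.
- `Gt` is weakly identified by the two-coordinate morphospace (above).
  This cascades: a cohort fitted into a wrongly-sagging regime can have its
  maximum stretching-force summary dominated by the first growth increment
  acting on the shared initial sagged shape, which is genotype-independent
  by construction. Force comparisons are trustworthy when simulated at the
  correct `Gt` regime.
- The displacement attribution is path-dependent by construction; only its
  additive structure and sign patterns are contract-guaranteed.
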