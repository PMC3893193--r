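---
title: "Static stability and control effectiveness from wind-tunnel force-balance data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static stability and control effectiveness from wind-tunnel force-balance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliderstab)
```

## The problem

Gliding performance of an animal (or a reconstruction of an extinct
one) is usually summarized by lift and drag coefficients and a glide
polar.  Those numbers say little about whether the animal could
actually *hold* a glide: a body moving through air experiences
perturbations, and whether the resulting torques restore or amplify
the perturbation — static stability — and how large a moment a given
appendage movement can generate — control effectiveness — are what
determine maneuverability.  `gliderstab` implements the full analysis
chain used in wind-tunnel studies of sting-mounted animal models:

1. reduce raw six-axis force/torque recordings to mean loads in the
   tunnel frame (`recording()`, `average_recording()`,
   `to_tunnel_frame()`);
2. nondimensionalize to the six aerodynamic coefficients
   $C_L, C_D, C_Y, C_l, C_m, C_n$ (`nondimensionalize()`);
3. estimate static stability derivatives $C_{m\alpha}, C_{n\psi},
   C_{l\phi}$ by per-replicate central differences over angle sweeps
   and locate/classify trim points (`central_difference_slopes()`,
   `find_trim_points()`);
4. estimate control-effectiveness derivatives
   $\partial C_{m,n,l}/\partial\delta$ for appendage deflections,
   and detect control reversal and roll/yaw function shifts
   (`control_derivative()`, `detect_reversal()`,
   `axis_shift_profile()`);
5. project to full scale and compute equilibrium-glide and comparative
   performance metrics (`to_full_scale()`, `equilibrium_glide()`,
   `performance_metrics()`, `turn_indices()`);
6. estimate body mass and center of mass by segment scaling and
   summation (`scale_segment()`, `total_mass_and_com()`).

A seeded synthetic data generator (`preset_config()`,
`generate_study()`) stands in for the wind tunnel, so every stage is
testable against analytically known truth.

## Frames, angles and sign conventions

All angles are degrees at every interface (and on disk); conversion to
radians happens once, internally.  Axes are the aerospace body
convention: $x$ forward along the body axis (upstream at zero
orientation), $y$ starboard, $z$ down.  Positive rotations are
starboard-wing-down roll $\phi$, nose-up pitch $\alpha$, and
nose-starboard yaw $\psi$.  The sensor-to-tunnel rotation is the
intrinsic yaw–pitch–roll composition
$R = R_z(\psi)R_y(\alpha)R_x(\phi)$.

The underlying data state only that three Euler rotations were
composed, not in which order or handedness; the package fixes the
standard aeronautics (Z–Y′–X″) convention as a single documented
constant.  Anyone replicating an external dataset should verify that
its mounting convention matches before comparing moment signs; the
column-mapping layer of `read_coefficient_table()` handles header
renaming but not axis conventions.

In the tunnel frame, drag is $-F_x$, side force $+F_y$, lift $-F_z$
(z points down), and $l, m, n$ are the moments about $x, y, z$.
Force coefficients divide by $q S$ with $q = \tfrac12\rho U^2$;
moment coefficients carry an extra snout-vent length $\lambda$.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| air density $\rho$ | 1.204 | kg/m³ | air at 20 °C; overridable per run |
| kinematic viscosity $\nu$ | 1.5e-5 | m²/s | air at 20 °C |
| tunnel speed $U$ | 6 | m/s | gives model Re $= U\lambda/\nu = 32{,}000$ at $\lambda$ = 0.08 m |
| reference area $S$ | 0.012 | m² | sprawled-posture planform of the 20 cm-span model |
| snout-vent length $\lambda$ | 0.08 | m | moment reference length |
| full-scale weight | 1.2 kg × g | N | midpoint of the 1–1.4 kg mass bracket |
| full-scale area / length / speed | 0.3 / 0.4 / 12 | m², m, m/s | isometric projection of the model geometry; reference flight speed |
| marginal band $\varepsilon$ | 0.001 | 1/deg | slopes within $\pm\varepsilon$ classify as marginally stable; small against typical measured slopes (~2–5 × 10⁻³/deg) |
| dominance ratio $r$ | 2 | – | roll- vs yaw-dominant if the derivative ratio exceeds 2 (or 1/2) |
| bank/crab angle $\theta$ | 60 | deg | conventional comparative value; arbitrary, configurable |

The marginal band has no canonical value in the stability literature —
"marginal" is an idealization of slope exactly zero.  $\varepsilon$ =
0.001/deg was fixed once, before any recovery experiment, as roughly
half the weakest designed-in stable slope of the synthetic postures;
it is a configurable argument everywhere it is used.

## Stability estimation choices

* **Per-replicate slopes.** Central differences are taken within each
  replicate run and then averaged, rather than differencing the
  replicate-mean curve.  The two orders coincide for balanced designs;
  the per-replicate order also yields a replicate dispersion for each
  slope.  Both are available (`order = "means"`).
* **Endpoints.** The central-difference scheme only covers interior
  grid angles; endpoints use one-sided first-order differences and are
  flagged in the output rather than silently mixed in.
* **Trim localization.** Zero crossings of the replicate-mean moment
  curve are found by linear interpolation between adjacent grid
  angles.  The sweep grid is coarse (5 deg); higher-order
  interpolation would invent structure the data cannot support.  For
  the sinusoidal moment curves of the synthetic model the linear
  interpolant is third-order accurate at the crossing (the curve's
  inflection sits at its zero), so recovered trims land well inside
  half a grid step of truth.
* **Boundary trims.** A zero crossing exactly at the first or last
  grid angle cannot be bracketed and is not reported as an interior
  trim; the synthetic sprawled posture intentionally has such a
  boundary zero at 90 deg in addition to its interior marginal trim
  at 0 deg.
* **Both trim conventions.** `find_trim_points()` reports the
  interpolated crossing *and* the nearest grid angle, since published
  tables may quote either.

## Control effectiveness choices

Derivatives are estimated at each angle of attack as the per-replicate
least-squares slope of the moment coefficient against deflection over
the full deflection grid (two levels reduce to a finite difference); a
secant between extreme deflections is available (`mode = "secant"`).
The default synthetic deflection grid is ±5 deg about neutral: the
derivative being estimated is a *local* partial derivative, and over a
sinusoidal response a ±5 deg chord attenuates the true slope by only
0.5 %, versus ~4 % for a ±15 deg chord.  Larger physical grids are the
reason the secant option exists.

Reversal detection treats derivative estimates inside the marginal
band as sign-indeterminate: they break a sign chain rather than anchor
a crossing, and a curve entirely inside the band is returned empty
with an `indeterminate` flag instead of manufacturing crossings from
noise.

## The synthetic generator

The generator emulates the study conditions: angle-of-attack sweeps
−15–90 deg in 5 deg steps, yaw sweeps −30–30 deg in 10 deg steps, five
replicates per treatment, deflection grids per appendage channel,
1000 Hz sampling, additive Gaussian sensor noise, and a small random
mounting misalignment drawn once per run (the dominant
replicate-to-replicate error source for a hand-remounted model).

Each surface follows a quasi-steady flat-plate closure: normal force
$C_N = A\sin\alpha_{loc}$, decomposed into lift
$a A \sin\alpha_{loc}\cos\alpha_{loc}$ and drag
$a(C_{D0} + B\sin^2\alpha_{loc})$, with side force following the same
law in the lateral plane scaled by a side-area fraction and attenuated
by $\cos\alpha$ (so the yaw plane becomes symmetric — flat — at
straight-down parachuting).  Moments are forces times moment arms.
Defaults $A = 2.2$, $B = 1.4$, $C_{D0} = 0.1$ give peak lift
coefficient 1.1 at 45 deg and a parachuting drag coefficient near 1.5,
the right magnitudes for a bluff multi-winged body at these Reynolds
numbers.  Noise defaults (force 5 mN, moment 0.2 mN·m per sample at
1000 Hz, misalignment sd 0.25 deg) were fixed once as plausible
six-axis-transducer figures.

Because the closure is built from levers and sines, its trim points,
stability slopes and control derivatives all have closed forms
(`analytic_pitch_trim()`, `analytic_pitch_slope()`,
`analytic_control_derivative()`), which is what makes end-to-end
parameter-recovery testing possible.  The four posture presets are
*designed* to reproduce the qualitative stability portrait of the
study animal's reconstructions — tent stable near 27 deg, biplane
stable near 16 deg, sprawled marginal, legs-down never stable, tail
reversal near 58 deg, asymmetric pronation shifting from roll to yaw
authority with angle of attack — by choosing area fractions, moment
arms and incidences accordingly.

What the generator does **not** emulate: stall hysteresis and
unsteady aerodynamics, wake interaction between surfaces, Reynolds
dependence (coefficients are exactly speed-invariant by construction,
which is itself a useful pipeline test), tare/bias drift, and tunnel
blockage or shear.  Passing recovery tests therefore demonstrates the
*reduction pipeline* is correct and unbiased under realistic noise;
it does not validate the flat-plate closure against a real animal.
Two closure artifacts worth knowing: the lift-based pitching moment
forces $C_m = 0$ at exactly 90 deg for every configuration, and the
roll/yaw dominance profile of asymmetric pronation is mirror-symmetric
about 45 deg (roll authority regrows above ~71 deg), so the monotone
roll-to-yaw shift is a statement about angles of attack below 45 deg.

## Equilibrium glide conventions

The default force balance equates the *resultant* coefficient
$C_R = \sqrt{C_L^2 + C_D^2}$ to weight:
$V = \sqrt{2W/(\rho S C_R)}$, $\gamma = \arctan(C_D/C_L)$.  At the
steep glide angles of interest, drag carries a large share of the
weight, so a pure-lift balance would overestimate speed; the lift
balance is still available (`balance = "lift"`).  With a caller-fixed
speed the solver instead reports whether the configuration can support
the weight at that speed — the relevant question for postures whose
trim produces too little force at the reference speed.  The banked and
crabbed turn indices ($L\sin\theta/W$, $Y\cos\theta/W$) follow the
classic comparative definitions; the horizontal projection on the
crabbed index is configurable since published usage varies.

Mass estimation is deliberately minimal: isometric (length-cubed)
segment scaling and weights-and-centers summation.  Allometric
long-bone regressions are supported as user-supplied
exponent/coefficient input rather than package constants, because
those coefficients belong to their source datasets.

## Problem sizes used by the tests and acceptance script

The validation suite generates its data at full study breadth but
shortened record lengths: the end-to-end recovery study is 4 postures
× 22 angles × 5 replicates (440 runs) at 2 s per record, and the
control-recovery experiment repeats a 7-treatment × 2-replicate design
over 100 seeds at 0.2 s per record.  Shorter records *raise* the
noise on each run mean (noise on a mean scales as $1/\sqrt{n}$), so
passing at 2 s is conservative with respect to the one-minute records
the acquisition emulates.  The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch at
the seed it is given and writes the recovered quantities as JSON.

## Known limitations

* The Euler-sequence convention is asserted, not inferred; replicating
  an external dataset with a different convention will flip moment
  signs.
* Trim points at sweep boundaries are not reported (no bracket).
* Combined multi-appendage deflections are out of scope, as are
  dynamic (eigenmode) stability, loess-smoothed presentation curves,
  and flow-field modeling.
* `reference_area_policy()` implements the single-baseline convention;
  coefficient values therefore depend on the chosen baseline posture
  and are not comparable across datasets normalized per-posture
  without re-reduction.
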