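---
title: "Threshold models and surrogate sorting in spiral inertial microfluidics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold models and surrogate sorting in spiral inertial microfluidics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(spiralsort)
```

## The physical model

In a spiral microchannel at channel Reynolds numbers of roughly 1–100,
suspended particles migrate across streamlines under two competing
effects. The net inertial lift force

$$F_L = \frac{C_L\,\rho_f U^2 a^4}{D^2}$$

(with $C_L$ a position-dependent lift coefficient, $U$ the velocity
scale, $a$ the particle diameter and $D = 2hw/(h+w)$ the hydraulic
diameter of the rectangular cross-section) pushes particles toward an
equilibrium between the centreline and the wall, while the curvature of
the channel sets up two counter-rotating Dean vortices whose strength is
measured by the Dean number $De = Re\sqrt{D/2R}$. The lateral speed of
that secondary flow follows the empirical correlation
$U_D = 1.8\times10^{-4}\,De^{1.63}$ (m/s), and the drag it exerts on a
particle is Stokesian, $F_D = 3\pi\mu U_D a$. Because $F_L \propto a^4$
and $F_D \propto a$, the ratio $R_f = F_L/F_D \propto a^3$ separates
particles by size: above a size threshold particles focus into a narrow
band near the inner wall and exit through one outlet; below it they stay
entrained in the vortices and disperse.

Two printed equations are dimensionally abbreviated in the source
literature: the lift expression without the fluid density and the drag
expression without the viscosity do not have units of force. This
package implements the dimensionally consistent standard forms shown
above; every scaling conclusion is unaffected.

Dense particles feel a third force along the curved path, the
centrifugal force

$$F_c = \frac{(\rho_p - \rho_f)\,\pi V^2 a^3}{6r},$$

negligible at neutral buoyancy but not for minerals such as talc
(2.75 g/ml in water). It opposes lift in the inner cross-section, so
focusing a dense particle requires $F_L = F_D + F_c$ rather than
$F_L = F_D$. Neither $V$ (particle tangential velocity) nor $r$
(trajectory radius) is constrained by the available data; the defaults
are $V = U$ and $r$ equal to the channel spiral radius, both explicit,
overridable parameters of `force_context()`.

## Threshold models

The focusing criterion is $a/x \ge 0.07$ with a characteristic length
$x$ that differs between models:

| model | $x$ | reference-channel threshold |
|---|---|---|
| TM1 | $D$ | 21.39 um (reports as 21 um) |
| TM2 | $h$ | 15.4 um (reports as 15 um) |
| TM3 | $(D+3h)/4$ | 16.90 um |
| TM4 | $cD$, $c \ge 1$ | 26.01 um at 2.75 g/ml |

TM4 generalises TM1 with a density coefficient
$c(\rho) = 0.127\rho + 0.867$ ($\rho$ in g/ml, valid 1.05–2.75 g/ml),
clamped below at 1 so that low-density particles recover TM1 exactly.
`calibrate_density_model()` reproduces those published coefficients from
two anchors: polystyrene at (1.05 g/ml, c = 1) and the talc threshold of
26 um inverted through $c = a_t/(0.07D)$.

Three numerical conventions matter here and are deliberate:

* **Internal values are never rounded.** Human-readable thresholds are
  rounded to the nearest micrometre (`round_threshold_um()`), or to the
  nearest half micrometre when working at the granularity of the
  ±2 um experimental size bins; the half-micron mode is what makes the
  intermediate-density thresholds report as 22.5 um (1.38 g/ml) and
  21.5 um (1.15 g/ml).
* **TM3 has two defensible displays.** The formula gives
  $0.07(D+3h)/4 = 16.90$ um on the reference channel, but the widely
  quoted 16.5 um is the average of the already-rounded TM1/TM2 values,
  $(21 + 3\cdot15)/4$. `tm3_display_threshold(round_chain = TRUE)`
  reproduces the latter; the model definition stays the formula.
* **`is_focused()` compares with a relative tolerance of 1e-9** so that
  a threshold reconstructed through the exact inverse
  `coefficient_from_threshold()` classifies its own anchor diameter as
  focused instead of failing by one ulp.
* **Eq-of-line densities are taken in g/ml**, the calibration's native
  unit; `density_coefficient()` rejects inputs that look like kg/m³
  rather than silently mis-scaling by 1000.

## The averaging test

A threshold predicted by TM1 may overestimate the true one. The
averaging test brackets the true threshold between a diameter known to
focus poorly (low) and one known to focus well (high), then bisects:
measure the replicated highest particle-recovery rate (hPRR) at the
bracket midpoint, compare against a well-focused reference, and keep the
half of the bracket consistent with the decision, stopping when the
bracket is narrower than `tol` (default 0.5 um, the scale at which
residual overestimation is negligible against ±2 um size bins). The
proposed threshold is the final upper bound — the smallest diameter
demonstrated to focus like the reference.

The comparison rule had to be chosen: the source record states only
"no significant difference" for triplicate measurements. We use a
**one-sided Welch two-sample t-test** of $H_1$: mean(test) <
mean(reference) at $\alpha = 0.05$. The directional alternative is the
question actually asked (is the midpoint *less* focused?), and it is the
only rule under which the benchmark comparison 77.6 ± 6.2 vs 91.6 ± 7.3
(n = 3) is significant (one-sided p ≈ 0.033) while 41.7 ± 3.4 vs
41.0 ± 4.8 is not — the two decisions the procedure's record marks. No
multiple-testing correction is applied across steps, matching the
procedure as practised. When both replicate sets are exactly constant
the t statistic degenerates and the decision falls back to the sign of
the mean difference, which is what lets deterministic oracles drive the
bisection in tests.

Midpoints are *truncated* to 0.1 um for reporting ((16.5 + 15)/2 =
15.75 reports as 15.7). By default the full-precision midpoint is
carried into the next bracket; with `rounded_midpoints = TRUE` the
truncated value is carried instead, reproducing the bench sequence
18, 16.5, 15.7, 16.1 exactly — both behaviours are demonstrable because
both are defensible.

## The reduced-order sorting simulator

`migrate()` and `simulate_population()` stand in for full CFD particle
tracing at desk scale. They integrate no trajectories; they preserve the
orderings and conservation laws the physics implies:

* **Focusing decision.** A particle focuses when its diameter reaches
  `0.84` times its density-corrected TM4 threshold. The fraction below 1
  encodes the empirically demonstrated overestimation of the
  hydraulic-diameter threshold: in the reference channel 18 um
  low-density beads — 84% of the 21.4 um TM1 prediction — are fully
  focused, while the same bisection evidence brackets the true
  threshold above 16.1 um. The value 0.84 is pinned between two facts
  the surrogate must honour simultaneously: 18 um low-density particles
  focus (ratio 0.842), and a TM1-threshold-sized particle raised from
  1.05 to 2.75 g/ml de-focuses (ratio 0.822). It is a structural
  constant of the surrogate, not a fitted parameter.
* **Placement.** Focused particles land deterministically at a lateral
  position (0 = outer wall, 1 = inner wall) that increases monotonically
  with the diameter-to-threshold ratio from the outlet-3/4 boundary
  (0.60 of the width) and saturates at 0.79, inside the second-innermost
  outlet — matching the observation that well-focused particles collect
  at outlet 4, not at the innermost outlet, and placing near-threshold
  sizes at the outlet-3/4 boundary, the genuinely ambiguous region where
  experiment and simulation disagreed.
* **Dispersal.** Unfocused particles draw their position from a normal
  with SD 0.25 of the channel width centred at 0.6, truncated to the
  Dean-mixed region [0.2, 1] (outlets 2–5). Every draw is seeded; an
  unfocused `migrate()` without a seed is an error, not a silent use of
  global RNG state.
* **Outlets** are the half-open bins $[k/n, (k+1)/n)$ over the lateral
  position, last bin closed, index increasing toward the inner wall.

A green simulator test therefore establishes ordering, conservation and
regime structure — not absolute recovery rates. Experimental PRRs
(91.6%, 77.6%, 52.4%, …) are not recomputable from first principles and
are deliberately not asserted.

## Synthetic populations

`generate_population()` emulates the experimental materials: regular
polymer microspheres (circularity 1, fixed diameter or uniform over a
±2 um bin) and cryogenically ground powders (circularity uniform on
[0.1, 1], diameters uniform on the bin, truncated below 100 um — the
collection filter). The within-bin uniform is a modelling choice: the
experiments treat a bin as one size class and record no within-bin
distribution. Circularity is generated and recorded but does not enter
the migration model (shape has only a small effect on inertial focusing
unless asymmetry is large); the field exists so a shape-dependent model
can be attached later. Replicated hPRR fixtures come from
`generate_prr_replicates()` (normal, clipped to [0, 100]%).

What the generator does **not** emulate: correlated density–shape
variation within a powder, particle–particle interactions (dilute-limit
assumption), deformability, and any within-bin size distribution other
than uniform.

## Defaults, units, degenerate inputs

* SI everywhere internally; config files carry explicit `{value, unit}`
  tags (`um`, `mm`, `g/ml`, `mPa.s`, `ml/min`) converted once on load.
* The spiral radius is not part of the published device description.
  It is a required geometry field with default 5 mm — a mid-spiral
  scale consistent with 10 loops at 300 um spacing — and every
  Dean-dependent output reports the radius it used.
* $U$ is the cross-section mean velocity $Q/(wh)$: this is the reading
  under which the published operating point (1.7 ml/min ↔ 0.257 m/s)
  and the Re = 1–100 window (0.021–2.1 ml/min) are reproduced. Printed
  flow-window values are truncated, not rounded (0.2576 prints as
  0.257; 0.0216 as 0.021).
* All-zero outlet counts, empty populations, brackets with
  `low >= high`, fewer than two replicates, and c < 1 under TM4 are
  errors with explicit messages, never silent defaults.

## Known limitations

Rectangular cross-sections only — the threshold family is demonstrably
not transferable to trapezoidal channels. No Navier–Stokes or
lattice-Boltzmann solving; the Dean velocity correlation is the only
secondary-flow model. Particle deformability is not modelled (rigid
particles assumed). The density-coefficient line is an interpolation
over 1.05–2.75 g/ml; outside that range predictions are flagged as
extrapolations.
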