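---
title: "A minimal half-center model of locomotor rhythm and steering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal half-center model of locomotor rhythm and steering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgrhythm)
```

## The model

A single limb's rhythm generator is reduced to two reciprocal leaky
integrators. Exactly one half-center is active at any time; its state $x$
rises from 0 according to

$$\dot x = x_0 + g\,u + r_{leak}\,x, \qquad x(0) = 0,$$

until it crosses the threshold 1, at which point it is reset to 0 and the
antagonist becomes active under its own $(x_0, g)$. The drive $u$ is a
dimensionless descending command proportional to the desired limb speed.
This is the feedforward skeleton of a spinal CPG: reciprocity is imposed
structurally (the inactive state is clamped at 0, so there is never phase
overlap), and the threshold and reset level are hard-coded to 1 and 0 —
each phase integrates over exactly one state-unit, which is what makes the
closed forms below possible. Generalised thresholds are deliberately not
exposed; rescaling $x_0$ and $g$ is equivalent.

For constant $u$ the active-phase ODE is linear with constant coefficients,
so the phase duration is exact:

$$\tau = \frac{1}{r}\,\log\!\Big(1 + \frac{r}{x_0 + g u}\Big),
  \qquad r = r_{leak} < 0,$$

and expanding $e^{r\tau}$ to first order in $r\tau$ gives the Taylor form
$\tau \approx 1/(x_0 + gu)$. Summing the two phases puts the cycle duration
into a rational form in the drive,

$$T_c(u) = \frac{a + b u}{\tilde a + \tilde b u + \tilde c u^2},
  \quad a = x_{01}+x_{02},\; b = g_1+g_2,\;
  \tilde a = x_{01}x_{02},\; \tilde b = x_{01}g_2+x_{02}g_1,\;
  \tilde c = g_1 g_2,$$

which for large $u$ behaves like $T_c \propto u^{-1}$ — the same family of
decaying power-type curves as the empirical speed–duration relation of
walking. The identity between the summed Taylor phases and the rational
form is asserted in the test suite at $10^{-12}$ relative tolerance across
random parameter draws.

### Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `x01`, `x02` | background offset rate of each half-center | state-units/s | −0.0007, 2.4256 |
| `g1`, `g2` | drive gain of each half-center | (state-units/s)/drive-unit | 0.6203, 0.4882 |
| `r_leak` | leak (self-feedback) rate, ≤ 0 | 1/s | −0.0094 |
| `u_offset`, `u_scale` | affine speed→drive regression | m/s | 0.1272, 0.2357 |
| `emp_coeff`, `emp_exp` | phenomenological power law $T_c = c\,V^{e}$ | s, – | 0.5445, −0.5925 |
| `swing_const` | speed-independent swing duration | s | 0.25 |
| `W` | interlimb step width | m | 0.15 |

The CPG defaults are a previously fitted optimum for cat overground walking
and ship as a JSON fixture (`inst/extdata/table_a1.json`); the speed maps
are the printed empirical regressions for the same preparation. None of
them are estimated by this package (fitting is out of scope).

Because `x01` is slightly negative, low drives are pathological: phase 1
needs $x_{01} + g_1 u > 0$, and with leak the stricter
$x_0 + g u > |r_{leak}|$ or the state saturates below threshold. All
admissibility failures are typed conditions
(`cpg_nonpositive_rate_error`, `cpg_saturation_error`,
`cpg_stalled_error` in the simulator) that carry the minimal admissible
drive, so callers can report valid speed ranges instead of silently
diverging.

`r_leak = 0` is accepted and routed to the Taylor formula — the exact
expression is 0/0 there but its limit is exactly the Taylor value, so the
API stays continuous at the singular parameter.

### Which phase is "swing"?

With the default parameters, phase 1 ($x_{01} \approx 0$, larger gain) is
strongly speed-modulated and phase 2 varies only ~0.21–0.27 s across the
walking range — i.e. phase 2 behaves like the near-constant swing phase
even though half-center 1 is conventionally drawn as the flexor. The
package exposes neutral indices 1/2 and documents phase 1 as stance-like
and phase 2 as swing-like; nothing downstream depends on the anatomical
label.

## The simulator

`simulate_cpg()` integrates the two-state system through time with event
detection and supports piecewise-constant drive schedules
(`input_signal()`). Two steppers are provided:

* **`exact`** (default): within each step the state is propagated with the
  closed-form exponential update and the threshold crossing is solved from
  the local closed form (per segment of a piecewise drive). Event times are
  accurate to roundoff, making this the oracle-grade engine for checking
  the analytic solutions — there is no discretisation error to hide behind.
* **`euler`**: a plain first-order scheme with the crossing located by
  linear interpolation inside the bracketing step. Its phase-duration error
  shrinks linearly in `dt`, and the test suite uses it to demonstrate
  genuine convergence behaviour (with the exact stepper a dt-refinement
  test would be vacuous).

Defaults: `dt = 1e-4` s, two orders of magnitude below the shortest phase
(~0.1 s) in the modelled speed range; both states start at 0 with state 1
active. Startup is otherwise unspecified by the model, and for constant
drive the steady rhythm is independent of the initial condition after the
first event.

## Validation against the empirical speed law

`validate_speed_law()` maps a grid of forward speeds through the affine
regression, evaluates the exact analytical $T_c$ and the power law, and
summarises agreement. Two R² flavours are reported:

* `r_squared` — squared Pearson correlation of the two duration vectors.
  This is the scale-free statistic corresponding to regressing one curve on
  the other, and it is the headline number.
* `r_squared_identity` — coefficient of determination about the identity
  line, $1 - \sum(T_a-T_e)^2 / \sum(T_e-\bar T_e)^2$, which additionally
  penalises systematic offset. Both appear in the JSON sidecar.

The default grid is 0.1–2.0 m/s in 0.05 m/s steps (39 points). This is a
package decision: it spans the cat walking range, stays inside the validity
window of the constant-swing approximation, and avoids the divergence of
the power law as $V \to 0$. The grid spec is recorded in the output
metadata so any other choice is reproducible. The exact (not rational)
solution is used for the headline curve; the Taylor/rational flavour is
retained as an option and changes the correlation by under $10^{-3}$
because $|r_{leak}|\tau \ll 1$ throughout the range.

```{r validate}
v <- validate_speed_law()
v
head(v$grid)
```

The empirical module also splits the cycle as swing ≈ 0.25 s (constant) and
stance = $T_c - 0.25$ s, valid only while $T_c$ exceeds the constant swing;
faster (running-type) gaits are rejected explicitly, as is any $V \le 0$.

## Steering

For two limbs driven at speeds $V_R$ and $V_L$, the per-cycle heading
change is the differential-drive relation
$\gamma = T_c\,(V_R - V_L)/W$ with $W$ the interlimb step width (0.15 m
default). $T_c$ is evaluated at the **mean** of the two limb speeds: the
underlying relation does not specify which speed sets the cycle, and the
mean is the only choice symmetric in the two limbs, consistent with
parametrising the heading surface by mean speed. $\gamma$ is therefore
exactly linear and antisymmetric in $\partial V = V_R - V_L$, and — because
$T_c$ decreases with speed — turning per step is strongest at slow speeds.

`simulate_walk_path()` accumulates headings and advances the body one
stride ($\bar V \cdot T_c$) per step. The heading is updated **before** the
translation (turn-then-translate), so the per-step $\gamma$ is literally
the angle between consecutive step vectors; `turn_first = FALSE` gives the
other order for sensitivity checks. Angles are radians internally, with
degrees available only at the reporting layer. The default trajectory
scenario (five steps, interlimb differential ramping linearly from 0 to
0.3 m/s, mean speeds 0.5/1/2 m/s) ships as a JSON fixture; the ramp shape
is a package decision — the qualitative pattern (curvature growing per
step, decreasing with mean speed) is what is asserted, not specific angles.

```{r steering}
sc <- steering_scenario(1.0)
simulate_walk_path(sc$V_R, sc$V_L)
```

## Numerical choices and degenerate inputs

* Event localisation: closed form for the `exact` stepper; linear
  interpolation (first order) for `euler`; step boundaries are split at
  drive-schedule change points, so crossings never straddle a segment.
* Stall detection is analytic for the exact stepper (rate ≤ 0, or
  saturation asymptote ≤ threshold) and derivative-based for `euler`; the
  stall time and active-state index travel in the condition object.
* Ties/boundaries: a crossing exactly at a step boundary is processed as a
  crossing; an unpaired trailing phase is discarded by `measure_cycles()`;
  a one-point validation grid is rejected (correlation undefined).
* CSV artifacts use fixed 9-significant-digit formatting so identical
  configurations give byte-identical files.

## What the tests do and do not show

All quantitative checks run against the model's own study conditions: the
fitted parameter set, the printed empirical regressions, and synthetic
random admissible parameter draws. Passing tests show internal consistency
(simulator ↔ closed forms ↔ rational identity) and faithful reproduction of
the published speed–duration agreement — not that the model generalises to
new animals, to running gaits (stance shorter than swing), to large
split-belt-style interlimb asymmetries, or to spin turning; all of these
are outside the model's validated range and explicitly out of scope. The
problem sizes used (39-point speed grid; 50–100 random draws; a few seconds
of simulated time at `dt = 1e-4` s) were chosen as comfortably sufficient
for those claims.
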