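---
title: "A lumped RC model of pressure-controlled ventilation and restrictor sizing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped RC model of pressure-controlled ventilation and restrictor sizing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventrc)
```

## The problem

When two patients must share one ventilator (dual-patient ventilation, a
last-resort arrangement), the machine runs at a single pressure setting
while the two patients may have very different respiratory mechanics.
The patient with the more compliant lung then receives too much volume.
A deliberate flow restriction in that patient's inspiratory limb brings
the delivered tidal volume back down — but only if the required
resistance can be calculated rather than found by trial and error on a
patient.  `ventrc` implements a deliberately minimal lumped
resistance–compliance model of one ventilator-tubing-patient branch that
is simple enough to invert directly for the required restriction, plus
the measurement procedures needed to obtain its parameters from bench
recordings.

## The model

One branch is a two-node RC network driven by the ventilator pressure
$p(t)$:

* the ventilator drives through a series resistance $R_s = R_v + R_r$
  (tubing resistance $R_v$, plus any added restrictor $R_r$ in the
  phase(s) where it sits in the flow path);
* the tubing compliance $C_v$ hangs on the node between that series
  resistance and the patient, at pressure $p_t$;
* the patient is an airway resistance $R$ in series with a lung
  compliance $C$ at pressure $p_\ell$.

$$
C_v \frac{dp_t}{dt} = \frac{p - p_t}{R_s} - \frac{p_t - p_\ell}{R}, \qquad
C \frac{dp_\ell}{dt} = \frac{p_t - p_\ell}{R}.
$$

In pressure-control mode the drive is modelled as an ideal square wave:
$p = \mathrm{PEEP} + P_\mathrm{insp}$ for the inspiratory fraction of the
breath (set by the I:E ratio) and $p = \mathrm{PEEP}$ for the rest.  The
model is therefore a two-phase switched affine system.  Within each
phase the solution is a matrix exponential; the breath-to-breath
periodic ("cyclic steady state") solution follows from the linear fixed
point $x(0) = x(T)$.  No time marching and no iteration is involved,
which is the point: the map from $R_r$ to tidal volume is cheap, smooth
and monotone, so the inverse problem is a bisection.

Assumptions worth stating explicitly:

* every element is linear — in particular a restrictor is represented by
  a proportional pressure-drop law $\Delta p = K_1 Q$, even though real
  orifice devices have a quadratic component;
* the drive switches instantaneously (no rise time, no flow limiting,
  no triggering);
* the two patient branches are independent: the model cannot represent
  the small cross-flow effect in which restricting one branch slightly
  increases the other branch's volume;
* parameters may differ between inspiration and expiration (up to eight
  per patient), though the bench characterisation below produces a
  single value for each.

### Tidal volume

Tidal volume is $V_T = C\,(\max p_\ell - \min p_\ell)$ over one steady
cycle, which equals the integral of positive patient flow.  One
subtlety: the lung-pressure maximum is *not* at the end of inspiration.
At the switch the tubing node is still above lung pressure, so the lung
keeps filling for a short moment into the expiratory phase.
`cyclic_steady_state()` therefore refines the extrema beyond its
sampling grid by root-finding on the patient flow within each phase.
Using phase-end pressures instead understates $V_T$ by roughly 0.4% at
the bench conditions — small, but of the same order as the agreement we
are trying to demonstrate.

### The $C_v = 0$ limit

With no tubing compliance the network collapses to one state with time
constant $\tau = (R_s + R)C$ per phase, and the periodic peak-to-peak
lung pressure has the closed form
$P_\mathrm{insp}(1-e_i)(1-e_e)/(1-e_i e_e)$ with
$e_i = e^{-t_i/\tau_i}$, $e_e = e^{-t_e/\tau_e}$.  This limit is handled
by an explicit one-state code path (not a small-$\epsilon$ hack) and is
exposed as `first_order_vt()`, which doubles as an analytic cross-check:
the full solver with $C_v = 0$ must agree with it to $10^{-9}$ L, and
does.

## Parameters and units

Units are fixed package-wide with no conversion layer: pressures in
cmH2O, volumes in L, times in s, resistances in cmH2O/(L/s), compliances
in L/cmH2O, respiratory rate in breaths/min.

| Quantity | Typical bench value | Meaning |
|---|---|---|
| `pinsp` | 15–25 | inspiratory pressure above PEEP |
| `peep` | 5 | baseline circuit pressure |
| `rr`, `ie_e` | 15, 2 | rate and I:E = 1:E |
| `r_v`, `c_v` | 22, 0.004 | tubing resistance and compliance |
| `r`, `c` | 10–12, 0.030–0.040 | patient airway resistance, lung compliance |
| `r_restrictor_insp` | 0–33 | added inspiratory restriction |

A restrictor placed in the inspiratory limb of a circle system is only
in the flow path during inspiration (the one-way valves route expiratory
flow through the other limb), so `r_restrictor_exp` defaults to 0 and
all validation configurations restrict inspiration only.

## Restrictor sizing

`vt_vs_restriction()` tabulates $V_T(R_r)$; `required_restriction()`
inverts it by bisection on an automatically doubled bracket starting at
[0, 50] cmH2O/(L/s), capped at 1000.  The convergence tolerance is
expressed in litres (default $10^{-4}$ L) because the clinically
meaningful quantity is the delivered volume, not the resistance.  A
target above the unrestricted volume is reported as infeasible — never
silently clamped — and a target below what the bracket cap can reach
raises a distinct error.

## Component characterisation

Pressure-drop/flow samples for a component are fitted to
$\Delta p = K_2 Q_m^2 + K_1 Q_m + K_0$ by iteratively reweighted least
squares with Tukey bi-square weights (tuning constant 4.685, at most 100
iterations, coefficient convergence $10^{-8}$ — the common defaults of
the standard robust-fitting tools, since only "bi-square" is specified
by the procedure being mirrored).  `model = "linear"` constrains
$K_2 = 0$; `model = "proportional"` additionally $K_0 = 0$, in which
case $K_1$ is the component's resistance and the only representation the
dynamic model accepts.  $Q_m$ is the mean of the two flowmeter readings
(`mean_flow()`), and samples from both phases are pooled.  For
constrained no-intercept fits the reported $R^2$ uses the uncentred sum
of squares, with the centred value also available — the two conventions
differ substantially for such fits and published values rarely say which
was used, so we report both.  Confidence intervals come from the final
weighted fit.  On noise-free data the bi-square scale estimate is zero
and the fit short-circuits to ordinary least squares, so robust and
non-robust results coincide exactly there.

The quadratic model keeps a free intercept (the full three-term law);
a non-return valve's cracking pressure (~1 cmH2O) shows up as the $K_0$
of the unconstrained linear fit and is not modelled further.

### Lung R and C from recordings

For a linear one-compartment patient,
$p(t) = b + R\,q(t) + V(t)/C$ where $V$ is lung volume above baseline.
`estimate_lung_rc()` regresses measured pressure on flow and volume to
recover $R = $ the flow coefficient and $C = $ the reciprocal of the
volume coefficient.  The volume regressor is taken from a `volume_L`
channel when the recording has one (flow analysers export integrated
volume); otherwise it is the running trapezoidal integral of flow.  In
either case it is detrended per breath: the true net volume over a
steady breath is zero, so the piecewise-linear interpolant through the
integral's values at detected breath starts is pure drift and is
subtracted.  This choice of a pressure-balance regression (rather than,
say, end-inspiratory occlusion analysis) is a design decision: it uses
every sample, needs no manoeuvres, and is exactly the model class the
simulator generates, so recovery is exact on noise-free data.

### Tubing compliance

With the patient end blocked, all delivered gas is stored in the line,
so $C_v$ is the slope of per-breath delivered volume against per-breath
pressure swing (through-origin regression across breaths).  Pressure
swings below 1 cmH2O are refused as unreliable.  A practical note on
sampling: the line flow is discontinuous at the drive switches, so
integrating a 50 Hz flow channel across the jump biases the delivered
volume by several percent purely as a sampling artefact; the volume
channel, integrated upstream at the instrument, does not suffer from
this, which is why the estimators prefer it when present.

## The synthetic-data generator

`generate_synthetic()` stands in for bench recordings: it samples the
steady-cycle waveforms at 50 Hz over 15 breaths (the recording
conditions of the characterisation experiments), adds independent
Gaussian noise per channel, and emits a second logger copy delayed by a
configurable inter-logger offset, emulating two flow analysers logging
on unsynchronised computers.  Default noise levels — 0.01 L/s on flow,
0.1 cmH2O on pressure, 0.001 L on volume — are typical instrument-grade
noise for clinical gas-flow analysers.  `coregister()` recovers the
offset as the integer-sample lag maximising cross-correlation of a
shared channel; because ventilation waveforms are periodic, the search
window should stay below half a breath period or the lag is ambiguous
modulo the period (the bench default of 4 s periods and sub-second
offsets is unambiguous with a window of ±1.9 s).

What the generator does *not* emulate: ventilator rise time and flow
limiting, nonlinear restrictor pressure drops, valve cracking
transients, drift or miscalibration of the analysers, and any coupling
between two branches.  Passing the recovery tests therefore shows that
the estimation procedures are correct for the model class and robust to
instrument-grade noise — not that the model captures every feature of
real hardware; that question is what the bench validation table is for.

## Numerical choices

* Phase propagation uses an eigendecomposition matrix exponential
  (machine-precision for these 2×2 RC matrices, with a scaled-Taylor
  fallback near defective cases).  Waveforms default to 1000 samples per
  cycle; extrema are refined by `uniroot` on the exact trajectory, so
  tidal volume does not depend on the grid.
* `simulate_transient()` is a deliberately independent oracle: classical
  fixed-step RK4 aligned to the switch times (default step 1 ms, refused
  if above a tenth of the fastest phase time constant), iterated until
  the cycle-start state changes by less than $10^{-9}$ cmH2O per breath.
  For a constant-coefficient affine system the RK4 update is itself an
  affine map, so it is applied through its action on basis vectors —
  bit-for-bit the same result as naive stepping at matrix-map cost.
* Bisection tolerances: $10^{-4}$ L on sized volumes; bracket cap 1000
  cmH2O/(L/s).
* Degenerate inputs error early and specifically: zero patient
  resistance with tubing compliance present (the state matrix needs
  $1/R$), zero total resistance in the one-state limit, flat flow in the
  estimators, all-equal flows in the fitters.

Problem sizes used by the test suite — 20 random parameter sets for the
oracle-equivalence property, 100 Monte-Carlo replicates for coefficient
recovery, 15-breath synthetic recordings — were chosen as the smallest
sizes at which the checked statistics are stable.

## Known limitations

* Agreement with the published bench predictions is limited to about 1%
  by the precision of the printed parameters themselves (a compliance
  printed as 0.040 is ±1.25% of predicted volume); the per-case
  deviation percentages in the source table cannot be reproduced more
  tightly than that from printed inputs.
* The restrictor enters the dynamics linearly; strongly orifice-like
  devices characterised with a large $K_2$ are only approximated by
  their proportional fit.
* Each branch is solved independently; dual-patient interaction through
  the shared ventilator is outside the model.
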