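---
title: "Sprint force-velocity profiling from a wheel-mounted IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sprint force-velocity profiling from a wheel-mounted IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelfv)
```

## The problem

Horizontal force-velocity (FV) profiling characterizes a sprinting
athlete by a linear relationship between the net propulsive force they
can produce and the speed at which they move. The line is summarized by
its intercepts — F0, the theoretical maximum force at zero velocity, and
V0, the theoretical maximum velocity at zero force — together with the
maximal power Pmax = F0·V0/4, the slope (usually normalized per kilogram
of moving mass) and the decrease ratio of force (DRF), which tracks how
fast mechanical effectiveness declines with speed.

For wheelchair rugby the measurement can come from a single IMU on the
drive-wheel hub: the gyroscope axis aligned with the axle reads the
wheel's angular rate, and multiplying by the wheel radius gives chair
speed. `wheelfv` implements the full chain from that raw angular-rate
trace to cohort-level FV statistics, including a wheelchair-specific
resistive-force model, so the two modelling choices a practitioner faces
— generic air friction versus chair rolling friction — can be compared
on the same sprints.

## From gyroscope to velocity

A sprint trace is cleaned in a fixed order (`process_sprint()`):

1. **Onset detection**: the sprint starts at the first sample whose
   *absolute* angular rate exceeds 10 °/s. The absolute value matters
   because a sensor on the left hub produces a negated trace; whether
   published pipelines thresholded signed or absolute values is not
   stated, and the absolute form is the only one that works for both
   mount sides.
2. **Conversion**: ω = (π/180)·gyro, V = ω·r. If the trace's dominant
   sign is negative the series is flipped so forward motion is positive.
3. **Filtering**: a 5th-order 4.5 Hz low-pass Butterworth, applied
   forward and backward (zero phase). Offline kinematics conventionally
   uses zero-phase filtering because a causal pass would delay the
   velocity rise and bias the acceleration time constant. The filter is
   run in direct-form II transposed with step-matched initial state and
   odd-reflection end padding, so constants pass with unit DC gain and
   the plateau is not distorted by edge transients.
4. **Crop**: the trace is cut at the global velocity maximum; ties break
   at the first maximum (earliest plateau attainment).
5. **Resampling**: linear interpolation onto exactly 1000 uniformly
   spaced points spanning onset to peak. The time axis stays in seconds
   — normalization is over sample count only — so the fitted time
   constant keeps physical units.

## The mono-exponential sprint model

Velocity is modelled as

$$V(t) = V_{max}\left(1 - e^{-(t - t_0)/\tau}\right), \qquad
  a(t) = \frac{V_{max}}{\tau} e^{-(t - t_0)/\tau},$$

with τ the acceleration time constant and t0 a small onset offset. The
printed form of this model is ambiguous about the sign attached to t0;
we adopt the reading in which V(t0) = 0, i.e. t0 shifts the sprint
start, with bounds ±0.5 s — a pure sign flip of t0 is observationally
equivalent, so nothing is lost. Fitting (`fit_monoexponential()`) is
bounded nonlinear least squares (Levenberg-Marquardt, cost tolerance
1e-10) on the 1000-point resampled trace with uniform weights, started
from Vmax at the observed maximum, τ at the time to 63.2% of it, and
t0 = 0; bounds are Vmax ∈ (0.5, 15] m/s, τ ∈ (0.05, 10] s. On failure
the solver restarts from up to five deterministically perturbed starting
points, so results never depend on global RNG state. Goodness of fit is
reported as RMSE and r² against the resampled measured trace.

## Resistive-force models

Both models feed the same net-force equation, `F_net = m·a + F_R`, with
resistive magnitudes taken positive and added. (The drag equation is
sometimes printed with a leading minus sign; subtracting it in the net
force would make the chair-specific model produce *less* force than the
air-friction model, the opposite of what the model comparison shows, so
the positive-magnitude convention is the only self-consistent one.)

**AF (air friction)** — the able-bodied sprinting convention:
SA = 0.2025·H^0.725·m^0.425·0.266 estimates frontal area from seated
stature and system mass; ρ = 1.293·(P/760)·(273/(273+T)) the air
density; k = 0.5·ρ·SA·0.9 the drag constant; F_R = k(V − V_wind)².
Indoor sprints assume V_wind = 0. The density formula divides pressure
by 760, a mmHg convention, even where source texts call the unit
hectopascal; `wheelfv` follows the formula literally — `pressure` is
"formula units with reference value 760" — and provides
`pressure_from_hpa()` / `pressure_from_mmhg()` converters to surface
the inconsistency rather than hide it.

**CRF (chair rolling friction)** — wheelchair-rugby-specific, built on
wind-tunnel and controlled roll-down measurements of rugby chairs:

$$C_D(V) = \frac{0.2955}{V + 0.0762} + 0.1608, \qquad
  C_L(V) = \frac{0.2099}{V + 0.1218} + 0.1666,$$

$$\mu = \frac{m a + C_D V^2}{m g + C_L V^2}, \qquad F_R = \mu m g .$$

Two parsing decisions deserve note, because the flattened printed
equations admit other readings:

* The drag/lift constants are read as the *rational* form above, not a
  linear one. Only the rational form yields finite high-speed asymptotes
  equal to the trailing constants (0.1608, 0.1666) — which is how
  velocity-dependent drag behaves physically — and package tests pin
  those asymptotes.
* The friction coefficient's sign pattern is resolved to
  (+ma + C_D V²)/(mg + C_L V²). This is the unique reading under which
  the CRF-to-AF net-force ratio at V → 0 is exactly 2 (since μ → a/g
  makes F_R = m·a, doubling the inertial term), matching the roughly
  2:1 F0 ratio reported for rugby cohorts under the two models.

The CRF formulation therefore counts inertia twice at low speed: μ
embeds m·a, and the net-force equation adds m·a again. That is how the
published computation is defined, and `wheelfv` reproduces it as the
default. A strict free-body variant that drops the inertial term from μ
is available (`net_force_trace(..., strict_freebody = TRUE)`) for
sensitivity analysis; it is excluded from the standard model comparison.

Net-force traces are evaluated on 1000 points spanning t0 to t0 + 6τ by
default — six time constants reach 99.75% of Vmax, a plateau for all
practical purposes.

## FV outcomes

`derive_profile()` regresses F_net on V by ordinary least squares over
all 1000 modelled points, unweighted and untrimmed. F0 is the intercept,
V0 = −F0/slope, Pmax = F0·V0/4, and the slope is normalized by system
mass. Only the per-kg normalization reproduces published slope
magnitudes (F0/(m·V0) ≈ 0.69 per kg for rugby-cohort CRF values), so it
is the primary field; the absolute slope is kept alongside. The maximum
of the instantaneous power curve is reported as a diagnostic
(`pmax_inst`) and should sit within ~15% of F0·V0/4 when the profile is
near-linear.

DRF is not given a formula in every source that reports it; `wheelfv`
adopts the ratio-of-force definition from the sprint-mechanics
literature: RF = 100·F_net/√(F_net² + (mg)²), the propulsive force as a
percentage of the total force the system supports, with DRF the OLS
slope of RF against V. Two checks justify this reconstruction: applied
to linear profiles built from published rugby cohort means (F0 = 282.1 N,
V0 = 4.631 m/s, m = 87.66 kg chair-specific; F0 = 139.1 N, V0 = 4.804
m/s air-friction), it returns −6.76 and −3.33 %·s/m, against published
−6.794 and −3.309. The system mass (not body mass) is used in the
denominator, consistent with the mass in the net-force equation.

## The synthetic generator

Because the original athlete recordings are not shareable, the package
ships a generator (`simulate_sprint()`, `simulate_cohort()`) that
inverts the forward model: a mono-exponential velocity curve is mapped
to gyroscope units, gyro = (180/π)·V/r, sampled at 60 Hz, and corrupted
with additive white Gaussian noise. Noise has two regimes: a 1 °/s
sensor floor while the chair is still (so onset detection sees a quiet
baseline, as a real stationary gyro does) and a much larger motion-phase
term (default 125 °/s) standing in for propulsion-induced push-cycle
ripple and vibration, which dominate measurement error in field data.
The motion-phase default was chosen analytically from the filter's noise
bandwidth so that velocity-fit residuals after the 4.5 Hz low-pass land
near 0.2-0.25 m/s with r² around 0.95 — the range reported for real
rugby sprints — and the acceptance suite checks the resulting band
(RMSE 0.1-0.35 m/s, r² 0.90-0.99) rather than a point value.

Cohort parameter distributions mirror a national rugby squad: body mass
69.5 ± 12.1 kg, chair mass 18.2 ± 1.2 kg, seated stature 1.19 ± 0.058 m
(published squad descriptives print stature in centimetres mislabelled
as metres; the reader normalizes any stature above 3 m by 100 with a
warning), wheel radius uniform on [0.25, 0.32] m, Vmax 4.7 ± 0.5 m/s on
[3.5, 5.5]. The time constant is τ = 2.9 ± 0.35 s on [2.0, 3.8]: for an
air-friction profile F0 ≈ m·Vmax/τ and the per-kg slope ≈ −1/τ, so
published cohort means (F0 ≈ 139 N, m ≈ 87.7 kg, Vmax ≈ 4.7 m/s, slope
≈ −0.33 per kg) pin τ near 2.9 s. Sprints last 14 s after a 1 s rest —
long enough for a plateau at that τ, consistent with a 45 m all-out
effort. Each athlete repeats two trials differing only in noise, and
all randomness flows from one explicit seed without touching the global
RNG.

What the generator does **not** emulate: per-push velocity ripple as a
structured oscillation (it is folded into white noise), curvilinear
motion, wheel slip, sensor bias drift, and timestamp jitter. Passing
tests therefore demonstrate that the pipeline recovers parameters from
mono-exponential kinematics under realistic noise *levels*, not that it
is robust to every artifact of field recordings.

## Numerical and degenerate-input choices

* fs is inferred from the median sample interval when not declared; a
  >1% disagreement with a declared value warns rather than errors,
  because consumer IMU clocks jitter.
* Rows with non-finite values are dropped and counted at ingestion;
  surviving samples are never altered.
* A trace whose maximum is at the first sample, an all-quiet trace
  (nothing above the onset threshold), velocity ranges below 0.5 m/s
  and zero-variance series for r² are all explicit errors, not silent
  results.
* Paired model comparisons average trials within athlete before the
  t-test; SEM is sd/√n with the n−1 sample standard deviation; no
  multiple-testing correction is applied across the five metrics,
  matching how such comparisons are reported.
* The reference "velocity correction" used to compare against other
  cohorts (`velocity_correct_reference()`) moves F0 along the reference
  FV line to a target V0 (F0 = −slope·m·V0). Published comparisons of
  this kind do not state their formula, so the result is flagged
  `best-effort reconstruction` and never claimed to reproduce any
  published corrected value.

## Problem sizes

The test and acceptance workloads use 60 Hz sprints of 8-14 s
(480-840 samples before resampling), cohorts of 6-18 athletes × 2
trials, a 3 × 3 noise-free recovery grid and 20-seed noisy replicates —
sizes at which the full suite completes in seconds while still
exercising every stage end to end.

## Known limitations

The CRF drag/lift constants are specific to rugby wheelchairs on the
surfaces they were measured on; other chair styles, tire pressures or
floors need their own coefficients. The double-counted inertial term is
reproduced deliberately (see above) and makes low-speed CRF force a
model convention rather than a free-body quantity. And because the
linear FV profile is derived from a fitted mono-exponential rather than
measured force, all outcomes inherit the fit's assumptions — a sprint
that is not mono-exponential (fatigue, collisions, pacing) will produce
a well-defined but physically questionable profile; inspect `rmse`/`r2`
before trusting it.

```{r example, eval = FALSE}
coh <- simulate_cohort(18, seed = 7)
tab <- cmd_profile(coh)                  # 72 rows: 18 x 2 trials x 2 models
cmp <- cmd_compare(tab, reference = reference_values())
format_comparison(cmp)
```
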