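# wheelfv

Sprint force–velocity (FV) profiling for wheelchair athletes from a
single wheel-mounted IMU.

A gyroscope on the drive-wheel hub measures wheel angular rate; with
the wheel radius this gives chair speed during an all-out sprint.
`wheelfv` turns that raw trace into the standard horizontal FV outcome
measures — and lets you compare the two resistive-force models a
practitioner has to choose between:

- **AF (air friction)** — the able-bodied sprinting convention: drag
  `k (V − V_wind)²` with `k = ½ ρ · SA · 0.9` from estimated frontal
  area `SA = 0.2025 · H^0.725 · m^0.425 · 0.266` and air density
  `ρ = 1.293 · (P/760) · 273/(273 + T)`.
- **CRF (chair rolling friction)** — wheelchair-rugby-specific: a
  dynamic friction coefficient
  `μ = (m·a + C_D V²) / (m·g + C_L V²)` with velocity-dependent
  drag/lift constants `C_D = 0.2955/(V + 0.0762) + 0.1608`,
  `C_L = 0.2099/(V + 0.1218) + 0.1666`, and `F_R = μ m g`.

The processing chain is: onset detection (first |gyro| > 10 °/s) →
conversion to translational velocity → zero-phase 5th-order 4.5 Hz
Butterworth low-pass → crop to peak velocity → resample to 1000 points
→ fit the mono-exponential sprint model
`V(t) = Vmax (1 − e^(−(t−t0)/τ))` → evaluate
`F_net = m·a(t) + F_R(t)` under each model → ordinary least squares of
`F_net` on `V` gives F0 (intercept), V0 (= −F0/slope),
Pmax (= F0·V0/4), the per-kg FV slope, and the decrease ratio of force
(DRF, the slope of `100·F_net/√(F_net² + (mg)²)` against velocity).

Cohort utilities aggregate per-sprint profiles, report mean ± SEM,
run paired CRF-vs-AF t-tests per metric, and compare against published
wheelchair cohort values. A synthetic-sprint generator with known
ground truth makes the whole pipeline testable end to end — the study
data such pipelines are built on are typically not shareable.

## Worked example

Simulate one realistic sprint, process it, and profile it under both
models:

```r
library(wheelfv)

cfg <- synthetic_sprint_config(vmax = 4.7, tau = 2.9, wheel_radius = 0.3,
                               duration = 14, gyro_noise_sd = 125, seed = 42)
trace <- simulate_sprint(cfg)
sys <- athlete_chair_system(body_mass = 69.51, chair_mass = 18.15,
                            stature = 1.1905, wheel_radius = 0.3)

kin <- process_sprint(trace, sys$wheel_radius)
fit <- fit_monoexponential(kin)
fit
#> <monoexp_fit> Vmax = 4.669 m/s, tau = 2.916 s, t0 = -0.029 s (rmse 0.230 m/s, r2 0.9614)

derive_profile(net_force_trace(fit, sys, model = "AF"), sys)
#> <fv_profile> [AF] F0 = 138.9 N, V0 = 4.83 m/s, Pmax = 167.8 W, DRF = -3.32, slope = -0.328 N s/m/kg
derive_profile(net_force_trace(fit, sys, model = "CRF"), sys)
#> <fv_profile> [CRF] F0 = 279.6 N, V0 = 4.75 m/s, Pmax = 331.8 W, DRF = -6.64, slope = -0.672 N s/m/kg
```

Reading the output: the fit recovers the simulated plateau velocity
(4.67 vs 4.7 m/s true) and time constant (2.92 vs 2.9 s) with residuals
of 0.23 m/s — the level field IMU data typically show. The
chair-specific CRF model then roughly doubles the estimated maximal
force and power relative to the generic air-friction model (279.6 vs
138.9 N; 331.8 vs 167.8 W) while leaving the theoretical maximum
velocity nearly unchanged (4.75 vs 4.83 m/s) — the signature
consequence of modelling rolling resistance explicitly: resistance
matters most while accelerating, hardly at all near top speed. DRF and
the per-kg slope steepen accordingly.

Cohort-level comparison:

```r
coh <- simulate_cohort(18, seed = 7)      # 18 athletes x 2 trials
tab <- cmd_profile(coh)                   # 72 profile rows (both models)
cmp <- cmd_compare(tab, reference = reference_values())
format_comparison(cmp)
```

which prints mean ± SEM per metric and model, five paired t-tests
(CRF − AF), and reference cohort rows velocity-corrected along their FV
line (flagged `best-effort reconstruction`).

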