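# tvorsim

Simulation and model fitting for the horizontal **translational
vestibulo-ocular reflex (tVOR)** — the otolith-driven reflex that rotates
the eyes to compensate for linear head motion along the interaural axis.

During an abrupt translation step, eye velocity shows two components: an
early component proportional to head *acceleration* and a sustained
component proportional to head *velocity*. The sustained component implies
that the brain mathematically integrates the otolith afferents' linear
acceleration signal before the common velocity-to-position neural
integrator — a "double integration" that cerebellar (nodulus/uvula) lesions
selectively impair. `tvorsim` packages the computational side of that
analysis for anyone studying otolith-ocular dynamics:

* **Stimulus kinematics** — trapezoidal sled profiles (0.26 g to 40 cm/s,
  320 ms plateau, 0.20 g stop; 20 cm displacement) and the geometrically
  ideal eye velocity `ω_ideal = d·ẋ_h / (d² + x_h²)` for a target at
  perpendicular distance *d*.
* **Dynamic block model** — head acceleration → otolith transfer function
  `O(s)` → a direct pathway (gain `G_acc`) in parallel with an
  acceleration-to-velocity **tVOR integrator** (gain `G_i`, pure `1/s` by
  default) → delay `τ` → target-distance geometry (`1/D`) → neural
  integrator `1/(s + 1/20)` → ocular plant `P(s)` (third-order Fuchs-type
  by default) → eye position `E_H`. Simulated as an LTI cascade with a
  zero-order-hold state-space discretization at 1 ms.
* **Synthetic sessions** — seeded trial generators (slow phase from the
  forward model + band-limited noise + raised-cosine quick phases) across
  eyes, directions, viewing distances (27/70 cm) and pre/post-lesion
  parameter regimes, with ground truth stored for recovery tests.
* **Slow-phase extraction** — quick-phase/saccade detection by
  Savitzky-Golay acceleration (>1400 °/s²) and jerk (>50,000 °/s³)
  thresholds with mask dilation; synchronization on the 1 cm/s chair-speed
  crossing; median ± quartile velocity profiles.
* **Two fitted models** —
  `ω_fit = g_v·ẋ_h(t−Δt) + g_a·ẍ_h(t−Δt)` by robust (Huber IRLS)
  regression with a 10–80 ms latency grid search, and bounded
  Levenberg–Marquardt estimation of the dynamic model's `(τ, G_acc, G_i)`
  with multi-start; epoch contrasts with t-based CIs.
* **Sensitivity analysis** — 1-D fractional sweeps and the 2-D
  `g_a × g_v` error surface around a fitted optimum.
* **Model comparison** — step-response and frequency-response simulations
  of three earlier tVOR architectures (Telford et al.; Green & Galiana;
  Angelaki et al.) against the double-integration model, including
  first- vs third-order plant substitution.

## Worked example

```r
library(tvorsim)

## one standard translation step and the model response
traj <- make_trapezoid_profile(stimulus_protocol())
abs(diff(range(traj$x)))              # 20.016  (cm travelled)
max(ideal_eye_velocity(traj, 70))     # 32.67   (deg/s, ideal at 70 cm)
sim <- simulate_tvor(model_parameters(), traj)
max(abs(sim$eye_velocity))            # 33.26   (deg/s, ~10% early overshoot)

## a synthetic pre/post-lesion session, one condition
pre <- model_parameters()             # G_i = 1, G_acc = 0.23 s, tau = 31 ms
ses <- generate_session(pre, lesion_params(pre),  # G_i x0.38, G_acc x0.87
                        n_trials = 4, distances = 70, eyes = "L", seed = 1)
ses <- synchronize_trials(mask_session(ses))

fit_linear_model(session_subset(ses, epoch = "pre", direction = "left"))
#> linear tVOR fit (both): g_v = 0.8243, g_a = 0.001184, delta_t = 46 ms, ...

fit_ep <- function(ep) optimize_parameters(
  session_subset(ses, epoch = ep, direction = "left"), n_starts = 2, seed = 1)
fit_ep("pre")
#> dynamic model fit: tau = 27.0 ms, G_acc = 0.2291, G_i = 1.053, ...
fit_ep("post")
#> dynamic model fit: tau = 26.0 ms, G_acc = 0.1897, G_i = 0.4089, ...
```

From this single condition the fitted integrator gain `G_i` drops by 61%
while the direct acceleration gain `G_acc` drops by 17% — the lesion
surrogate selectively removes the integrated (velocity) component, the
signature the full test suite recovers with confidence intervals across
eight conditions. The fitted `g_v ≈ 0.82 (deg/s)/(cm/s)` matches the ideal
geometric gain at 70 cm (`(180/π)/70 ≈ 0.818`), while `g_a` is absorbed by
the plant lag and latency, which is why the dynamic-model fit — not the
linear fit — is used for gain contrasts.

A command-line wrapper over the same functions is installed at
`inst/cli/tvor.R` (subcommands `stimulus`, `synth`, `simulate`,
`preprocess`, `fit-linear`, `fit-model`, `sensitivity`, `compare-models`,
`freq-response`, `run`).

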