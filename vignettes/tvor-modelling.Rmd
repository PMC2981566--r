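---
title: "Modelling the translational vestibulo-ocular reflex with tvorsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the translational vestibulo-ocular reflex with tvorsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvorsim)
```

## The scientific problem

When the head translates along the interaural axis, keeping the fovea on a
target requires an eye rotation whose angular velocity depends on target
distance: for a target at perpendicular distance $d$ and head position
$x_h$,

$$\omega_{ideal}(t) = \frac{d\,\dot x_h(t)}{d^2 + x_h(t)^2},$$

the time derivative of the gaze angle $\arctan(x_h/d)$. The otolith organs,
however, transduce linear *acceleration*. A sustained, velocity-proportional
eye response to a translation step therefore requires a central
*mathematical integration* of the afferent signal — and a second
integration (the common velocity-to-position neural integrator, NI) to hold
eccentric eye position afterwards. `tvorsim` implements a linear
block model with exactly this double integration, the estimation machinery
to fit it to (synthetic) eye-movement recordings, and simulations of three
earlier tVOR architectures that lack a true second integration.

## The dynamic model

The forward model is an LTI cascade driven by linear head acceleration
$\ddot x_h$ (cm/s²):

1. **Otolith dynamics** $O(s) = k\,(1 + T_{lead}s)/(1 + T_{lag}s)$. The
   source publications for the first-order afferent approximation do not
   print their constants, so the default is the identity configuration
   ($T_{lead} = T_{lag}$, $k = 1$): a pure gain, which every test also
   holds itself to. The constants are ordinary configuration
   (`model_parameters(otolith = ...)`) for users who want afferent
   dynamics.
2. **Two parallel central pathways**: a direct pathway of gain $G_{acc}$
   (units s: cm/s² → cm/s) and the **tVOR integrator** pathway
   $G_i/s$ (leaky $G_i/(s + 1/T_c)$ optionally). Their sum is a linear
   eye-velocity command.
3. **Delay** $\tau \in [0, 75]$ ms, implemented as a fractional-sample
   linear interpolation of the input so that fits over $\tau$ have a smooth
   objective. (In an LTI chain the delay commutes with every block, so its
   position is immaterial.)
4. **Geometry**: division by $D$ (cm) converts the linear command to
   angular demand (small-angle form, matching the block diagram; the exact
   $\arctan$ geometry differs by $<0.3\%$ over the $\pm 10$ cm excursion at
   27–70 cm viewing distances).
5. **NI** $1/(s + 1/T_{NI})$ with $T_{NI} = 20$ s, and the **ocular
   plant** — third-order with time constants 0.224, 0.013, 0.004 s (the
   classic three-pole description of the globe and orbital tissues;
   unity DC gain), or first-order with 0.25 s. A first-order plant constant
   printed elsewhere as "0.25 ms" is read as 0.25 s, consistent with the
   0.26–0.28 s plant constants of the single-integrator models.

Eye position is the chain output; eye velocity is its derivative, simulated
through the same chain with the differentiation folded analytically into
the NI block ($s/(s+1/T_{NI})$, still proper).

### Default gains

The defaults `G_i = 1`, `G_acc = 0.23` s, `tau_delay = 0.031` s,
`distance = 70` cm define the reference ("pre-lesion") regime. $G_i = 1$
makes the sustained response equal the ideal small-angle velocity. No
fitted gain values are available to copy, so $G_{acc}$ was chosen once so
that the model sits in the qualitative regime the lesion analysis
describes: peak eye velocity more sensitive to the acceleration gain,
final eye position more sensitive to the velocity (integrator) gain, and
an early velocity overshoot (~10% above ideal) from the acceleration
pathway "catching up" for the latency. Under the standard stimulus these
constraints bracket $G_{acc}/G_i$ to roughly 0.22–0.24; 0.23 is fixed and
not revisited. The post-lesion surrogate (`lesion_params()`) scales
$G_i \times 0.38$ and $G_{acc} \times 0.87$.

## Numerical simulation

All blocks are rational and of order $\le 2$, so the package builds the
*series interconnection* of per-block state-space realizations and
discretizes the combined system once with a zero-order hold (matrix
exponential of the augmented system) at the 1 ms eye-sampling step.
Two numerical choices matter and are tested:

* **Why not one companion form?** Multiplying the chain into a single
  6th-order transfer function gives companion-matrix coefficients spanning
  seven orders of magnitude (plant poles at 4.5–250 s⁻¹ against the NI pole
  at 0.05 s⁻¹); the matrix exponential of that realization loses ~5 of the
  16 available digits. The block-cascade realization keeps entries
  $O(1/T_{min})$ and is accurate to machine precision.
* **Why fold the derivative into the NI block?** Reading eye velocity as
  $C A x + C B u$ from the position realization differences nearly equal
  fast plant states scaled by $1/T^2 \approx 6\times 10^4$, amplifying any
  discretization error ~4000-fold at low frequencies. Folding $s$ into the
  slowest block avoids the cancellation entirely. The test suite pins the
  result: simulated gain and phase match the analytic transfer function
  evaluated at $s = 2\pi i f$ to $<1\%$ and $<1°$ over 0.01–4 Hz.

The trapezoidal chair profile is sampled at the chair transducer's native
2 ms period and linearly interpolated onto the 1 ms grid; position is
trapezoidal integration of the sampled velocity. Frequency responses are
measured as the paper-style "simulate and fit a sinusoid" procedure:
sinusoidal head velocity $\sin(2\pi f t)$ (whose acceleration integrates to
a zero-mean sinusoid, so the pure integrator acquires no offset), a settle
time of four times the slowest time constant, then a least-squares
sine/cosine/constant fit over five steady-state cycles.

## The synthetic-data generator

No recordings are distributable, so sessions are synthesized with the
statistical structure the analysis pipeline assumes: slow-phase velocity
from the forward model, plus

* **measurement noise**: additive Gaussian velocity noise, low-pass
  filtered (2nd-order Butterworth, `filtfilt`) and rescaled to an exact
  standard deviation (default 2 deg/s). The bandwidth default is 20 Hz:
  noise concentrated below the band in which the fast-phase detector's
  differentiators operate, as in real coil recordings where slow-phase
  noise sits far below the saccade thresholds. (At 50 Hz bandwidth the
  *jerk of the noise alone* exceeds the 50,000 °/s³ criterion at most
  samples and the detector would mask essentially the whole trace.)
* **quick phases**: raised-cosine velocity pulses (20–40 ms, 20–60 deg/s,
  random sign) at Poisson times (default 1 s⁻¹). The amplitude/duration
  ranges guarantee peak accelerations above 1400 °/s² **and** peak jerks
  far above 50,000 °/s³, i.e. the pulses are detectable *by construction* —
  they model the detection problem, not saccade physiology.

Sessions alternate leftward/rightward trials within each epoch × eye ×
distance cell, and every trial records its sub-seed and generating
parameters, so any trial and the whole session are exactly reproducible.
What passing recovery tests on these data show is that the *estimation
machinery* is unbiased and correctly scoped; they cannot show robustness to
features the generator omits — pursuit contamination in target-on trials,
vergence changes, the anti-compensatory deceleration nonlinearity, or
non-Gaussian coil noise.

## Slow-phase extraction and fits

Fast phases are flagged where Savitzky–Golay estimates (default 15 ms
window, cubic) of eye acceleration or jerk strictly exceed 1400 °/s² or
50,000 °/s³, and flagged runs are dilated by 10 ms per side to remove
saccadic shoulders. The differentiation scheme and dilation margin are not
prescribed anywhere and are therefore configuration with documented
defaults. Trials synchronize at the first chair sample with speed
$\ge 1$ cm/s; profile percentiles use linear interpolation between order
statistics (`quantile` type 7).

The **linear fit** pools unmasked samples across trials of one condition
and, for each latency on the 10–80 ms × 2 ms grid (the chair sample
period), estimates $g_v, g_a$ by iteratively reweighted least squares with
the Huber $\psi$ ($k = 1.345$, the conventional 95%-efficiency constant;
the loss is configurable since only "robust least-squares" is specified).
The IRLS implementation returns the exact LS solution when the residual
scale collapses to zero, which the machine-precision recovery test
exercises; `MASS::rlm` serves as the independent cross-check on
contaminated data. The grid latency with the smallest squared residual
wins; ties break to the smallest latency.

The **dynamic-model fit** minimizes the concatenated unmasked
measured-minus-simulated eye-velocity residuals over
$(\tau, G_{acc}, G_i)$ with `minpack.lm::nls.lm` — a Levenberg–Marquardt
trust-region implementation that accepts the required bounds
($\tau \in [0, 75]$ ms, gains $\ge 0$) — from five seeded starts by
default (initialization is unspecified in the source analyses; the
default start is $(30\ \mathrm{ms}, 0.1, 0.5)$ plus log-uniform
perturbations). Noiseless self-generated data are recovered to
$<1\%$ (gains) and $<2$ ms (delay); at the default noise a 20-trial fit
stays within 5% and 3 ms, and 50-replicate Monte-Carlo bias is below 2%.

**Sensitivity sweeps** vary one parameter as a fractional change
$f \in [-1, 1]$ ($f=-1$: zero; $f=+1$: doubled; the delay moves additively
toward its bounds so $f = 0$ remains the baseline) and report peak
velocity and 500 ms position as ratios to baseline and the error function
as percent of baseline. "Final eye position (at 500 ms)" is measured
500 ms after motion onset throughout (the step itself lasts 681 ms).
Sweeps are taken at a fitted optimum of a *noisy* reference series — on a
noiseless self-generated series the baseline error is identically zero and
percent-of-baseline is undefined. In the sensitivity context the field's
lowercase symbols map as $g_a \mapsto G_{acc}$, $g_v \mapsto G_i$ (the
integrated pathway carries the velocity-proportional component). The 2-D
surface grid defaults to 41 × 41 (resolution is a display choice).

## Prior architectures

The three comparison models are rebuilt from their printed descriptions,
with constants declared in one place (`prior_model_defaults`) and a common
31 ms input delay; outputs are rescaled to matched peak eye velocities, as
comparisons across effective viewing distances require:

* **telford** — leaky acceleration-to-velocity integrator (250 ms) in
  series with a high-pass stage (50 ms), then the common NI; no plant.
* **green_galiana** — the NI as the single central integrator, with a
  first-order 0.27 s plant whose low-pass lag stands in for the second
  integration.
* **angelaki** — green_galiana preceded by first-order otolith afferent
  lead-lag dynamics (defaults $T_{lead}=0.1$ s, $T_{lag}=0.016$ s, unity
  gain — placeholders marked configurable; the canal input of the
  published model is omitted for pure translation).

The comparative findings the suite asserts — and asserts again with every
prior-model constant moved ±20% — are: the double-integration model
maintains the most eye velocity through the cruise and at motion end; it
alone holds eccentric position afterwards (NI decay only, $<3\%$ in
500 ms); the single-integrator architectures drift back to zero within
about a second; and substituting the third-order plant for the first-order
one visibly degrades their cruise-phase velocity maintenance. One printed
claim did not survive literal reconstruction: with the 50 ms high-pass
stage in series, the Telford architecture's step response is *not* nearly
identical to Green/Galiana's (peak-scaled RMS difference ≈ 0.47, driven by
a cruise-phase reversal) — the similarity would require that stage to be
transparent in the step's band. The package keeps the printed constants
and reports the RMS difference as a quantity rather than asserting a
threshold on it.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run entirely on synthetic
data generated at call time: sessions of 2–6 trials per condition cell for
fitting tests, 100 trials for detector operating characteristics, 200
trials for the law-of-large-numbers check, and 50 Monte-Carlo fit
replicates — sizes chosen so the full suite completes in about a minute on
one core while leaving every statistical margin comfortable. Degenerate
inputs are contracts, not accidents: zero gains give exactly zero output;
a vanishing peak speed gives a vanishing trajectory; an all-masked trial
contributes nothing and an all-masked series is an error; a stationary
chair cannot be synchronized and is rejected with a warning; exact linear
data return exact regression coefficients.

## Known limitations

The model is linear: it reproduces neither the smaller-than-predicted
anti-compensatory response during deceleration (a real asymmetry the
linear chain cannot express) nor any high-frequency nonlinearity.
Target-on (visually assisted) trials are generated with the same dynamics
as target-off trials and are excluded from fits, as the fitting procedures
assume translation in darkness. The otolith and prior-model constants that
live in publications outside this package's scope are labelled
placeholders; conclusions that depend on them are tested under ±20%
perturbation, and anything sharper needs the original values.
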