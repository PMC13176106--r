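---
title: "Isovolumic relaxation strain imaging: model, simulator and statistical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isovolumic relaxation strain imaging: model, simulator and statistical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivsi)
```

## The problem

Diastolic dysfunction — the heart's failing ability to relax and fill —
precedes systolic decline in pressure-overload heart failure, yet the
conventional echocardiographic indices (E/A, E/E′) are notoriously prone to
pseudonormalization: as the ventricle remodels, the indices drift back into
the normal range while the underlying relaxation keeps deteriorating.
Active relaxation, driven by sarcoplasmic-reticulum calcium reuptake, is
best isolated during the *isovolumic relaxation time* (IVRT): the short
interval between aortic valve closure (AVC) and mitral valve opening (MVO)
in which ventricular volume is constant and everything that happens is
active. In the mouse, the standard preclinical model, the IVRT lasts only
~15–25 ms at heart rates of 400–450 bpm, which is why it is usually ignored
— and why resolving it requires acquisition well above 200 frames/s.

This package implements *isovolumic relaxation strain imaging* (IVSI) as a
reusable pipeline: starting from per-segment speckle-tracking strain traces
and valve-event annotations, it smooths, differentiates, windows on the
IVRT, and extracts four quantities per signal — maximal value, minimal
value, maximal acceleration, minimal acceleration — each signed and in
absolute value, per segment and averaged across segments. The headline
metric is the **minimal acceleration of the radial strain rate**, the most
negative time derivative of the radial strain-rate curve inside the IVRT.
Impaired (slower) active relaxation makes the strain-rate downstroke less
abrupt, so |min accel| falls — before any conventional index moves.

## Sign conventions and definitions

Contraction during systole is positive, relaxation in diastole negative:
radial strain (wall thickening) rises to a positive systolic plateau,
longitudinal strain (apex-to-base shortening) is its sign-mirrored
counterpart. Strain is carried in percent throughout; strain rate is its
time derivative (%/s). The *acceleration* of a signal is the first
derivative of that signal's rate curve: for strain rate that is d(SR)/dt,
for strain it is the second time derivative (the same quantity when SR is
derived from strain), and for velocity it is dv/dt.

## The processing chain

1. **Smoothing.** Raw strain is filtered once with a low-pass Butterworth
   filter, cutoff 20 Hz (physical Hz), order 2 — the parameters used by
   clinical speckle-tracking software. Derivative stages are *not*
   re-filtered. Two application modes exist: `single_pass` reproduces the
   causal filter with its $|H(f)| = (1+(f/f_c)^{2n})^{-1/2}$ magnitude law
   (gain $1/\sqrt2$ at the cutoff), while the default `zero_phase`
   (forward–backward) mode squares the magnitude and removes the group
   delay. Zero-phase is the default because the IVRT window is anchored to
   valve-event *times*: a causal filter's group delay (~11 ms at 20 Hz,
   order 2 — most of an IVRT) would shift the waveform relative to the
   window. The filter is applied over odd-reflection end pads so start-up
   transients die inside the pads and the DC gain is exactly 1.

2. **Differentiation.** Second-order central differences in the interior
   and second-order one-sided stencils at the ends. The one-sided ends
   matter: first-order endpoints would contribute an $O(\Delta t)$ error
   (about 1.6 % on a 5 Hz sinusoid at 1000 Hz) where the second-order form
   stays at 0.03 %.

3. **Windowing.** Windows are derived from the valve events — IVRT =
   [AVC, MVO], systole = [cycle start, AVC], early diastole = [MVO, end of
   E wave], full diastole = [MVO, cycle end] — keeping every sample inside
   the closed interval (the IVRT is short; discarding boundary samples
   biases extrema). A window spanning fewer than 3 samples raises a
   resolution error: this is the frame-rate requirement made executable.
   An 18 ms IVRT needs ≥ 150 Hz to be representable at all and ≥ ~800 Hz
   before the windowed extrema stabilise.

4. **Extraction.** Per signal and segment: max/min value and max/min
   acceleration inside the IVRT, signed and absolute. "Average" metrics
   are the unweighted mean of per-segment values, not the metric of the
   segment-averaged curve — segments stay exchangeable and per-segment
   localisation (which segments deteriorate first) remains available.
   Both signed and absolute variants are always emitted because published
   group contrasts are stated on absolute values while model coefficients
   are naturally signed.

## The cardiac-cycle simulator

No public murine strain traces with valve-event annotations exist, so the
package carries a parametric simulator that is itself first-class, tested
code. Its defaults *are* the study conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `heart_rate` | 420 bpm | anaesthetised mouse, target range 400–450 |
| `frame_rate` | 1000 Hz | IVRT spans 18 samples |
| `peak_radial_strain` | 25 % | systolic plateau |
| `ivrt_ms` | 18 ms | AVC → MVO |
| `tau_active` | 8 ms (sham) / 16 ms (TAC) | active-relaxation time constant |
| `segment_gains` | 0.88–1.12 | mild segment heterogeneity |
| `noise_sd` | 0.5 % strain | additive measurement noise |
| `tau_between_sd`, `tau_residual_sd` | 0.8 ms | biological variability |

Phases are C¹-continuous by construction — the headline metric is a second
derivative and must not be dominated by spline kinks:

* systole: cosine ramp $S = P\,(1-\cos(\pi t/t_{AVC}))/2$, zero slope at
  both ends;
* active relaxation from AVC: $S = P\exp(-\varphi(u)/\tau)$ with the
  smooth onset $\varphi(u) = u^3/(3w^2)$ for $u \le w$ (where $w$ is the
  IVRT duration) continuing linearly as $\varphi(u) = u - 2w/3$ beyond
  MVO. Strain rate is zero at AVC, peaks (most negative) exactly at MVO,
  and decays exponentially with time constant $\tau$ through the E wave;
* late diastole: a raised-cosine taper returns strain to exactly zero at
  cycle end, plus a small raised-cosine atrial-kick bump.

A *pure* exponential leaving the systolic plateau would put a strain-rate
kink at AVC whose second derivative is unbounded, making the metric an
artefact of the sampling grid; the cubic onset is the mildest smooth
alternative that keeps the decay exponential where the Weiss picture
demands it. It also yields an exact closed form for the headline metric:

$$\left|\min_{IVRT} \frac{d\,SR}{dt}\right|
  = q\,\frac{P\,g}{(w^2\tau)^{2/3}},\qquad
  q = e^{-v^3/3}\,(2v - v^4),\; v^3 = 3-\sqrt7,\; q \approx 1.0346,$$

attained in the interior of the window — strictly decreasing in $\tau$, so
prolonged relaxation (the TAC phenotype) lowers the metric, exactly the
behaviour the method exploits. The 1000 Hz discretised pipeline agrees
with this law (evaluated densely at 10 kHz) to within 2 %.

The pressure trace shares the same $\tau$: systolic rise and fall, then
$P = P_{AVC}e^{-u/\tau}$ during the IVRT, so the Weiss method (log-linear
regression of pressure on time over AVC→MVO, $\tau = -1/\text{slope}$)
recovers the simulator's relaxation constant exactly — a deliberate
cross-modality consistency check.

TAC is modelled purely as $\tau$ prolongation, with an optional
`tac_peak_decline` flag adding progressive systolic (peak strain) decline
for late-stage disease. Sham vs TAC defaults (8 vs 16 ms) are stand-ins
chosen to be physiologically plausible — no quantitative murine relaxation
kinetics for TAC exist to calibrate against — and are documented as such.

**What the simulator does not emulate:** respiration artefacts and beat
selection, speckle decorrelation and tracking drift, probe-angle
dependence, pericardial constraint, heart-rate variability within a
session, and any coupling between afterload and the strain waveform.
Passing tests therefore show that the *pipeline* recovers what the
kinematic model encodes at realistic noise, not that the instrument chain
is validated on real animals.

## Statistical layer

* **Welch's t-test** for two-group comparisons; degenerate zero-variance
  input follows the convention p = 1 for equal means.
* **Linear mixed-effects model** `value ~ group + day + (1 | animal_id)`,
  REML via lme4 with Satterthwaite degrees of freedom via lmerTest and
  Wald intervals on those df. A random intercept per animal is assumed
  (random slopes are not): with daily imaging over two weeks the dominant
  dependence is animal-level. Singular fits are flagged, not fatal; if
  the mixed fit is impossible (zero residual variance), the model
  degenerates to OLS — the correct singular limit.
* **BH-FDR** over one family per analysis run: all metric–effect rows of
  the reported panel in a single adjustment (configurable to per-effect
  families). One run = one family is the most conservative reading
  consistent with a single `p.adjust` call over a reported panel.
* **ICC(A,1)** — two-way random, absolute agreement, single measure —
  with McGraw–Wong F-based intervals, for observer reproducibility. The
  variant is an assumption (the single-measure absolute-agreement form is
  the strictest of the common choices) and is fixed, documented, here.
* **Bland–Altman** bias and 1.96·SD limits of agreement.
* **A priori power**: smallest integer group size whose exact
  noncentral-t power reaches the target. For the pilot summary
  (means 0.022 vs 0.056, SDs 0.017 and 0.023, equal-n pooled SD) Cohen's
  d = 1.68; the two-tailed 0.05/0.80 design then requires **7** per
  group (power at n = 6 is 0.746), while a one-tailed design requires 6.
  Published power analyses quoting 6 per group for this effect size are
  consistent with the one-tailed calculation; the package reports both
  and defaults to two-tailed. `cohens_d` uses the equal-n pooled form
  because pilot groups of equal size are the intended use.

### Calibration evidence the package computes for itself

`detection_study()` simulates independent sham-vs-TAC cohorts
(10/group, days 1–14, TAC τ doubled, default noise), runs the full trace
pipeline and demands a per-day Welch detection (TAC lower, p < 0.05) from
day 4 onward; `coverage_study()` checks that the mixed-model 95 % interval
for a known group effect covers it at nominal rate. Both are asserted in
the test suite (100 and 500 replicates respectively; the acceptance script
re-runs them at 40 and 300 replicates to stay fast).

## Numerical choices and degenerate inputs

* Time is seconds internally, everywhere; readers convert millisecond
  columns via a flag.
* Trace CSVs are written at full (17 significant digit) precision so a
  write/read round trip is bit-identical; metrics and stats tables are
  fixed-precision, diff-friendly TSV.
* Missing samples: linear interpolation across gaps of ≤ 3 samples;
  longer gaps or boundary gaps are rejected — differentiation cannot be
  trusted across them.
* Uniform-grid tolerance: relative step jitter below 1e-6.
* The IVRT window keeps boundary samples (closed interval, with a
  1e-6-sample floating-point guard on the boundary comparison).
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; cohort simulation is bit-reproducible under its
  seed.
* Problem sizes in the shipped tests — single cycles at 1000 Hz, dense
  oracles at 10 kHz, 100-replicate detection and 500-replicate coverage
  studies — were chosen as the smallest sizes at which the Monte-Carlo
  error of each assertion is comfortably below its tolerance.

## Known limitations

* The simulator's TAC phenotype is a relaxation-constant stand-in, not a
  fitted disease model; absolute metric values are in simulator units
  (%/s² for strain-rate acceleration) and are not comparable to
  instrument exports whose acceleration units are undocumented.
* The mixed model covers random intercepts only; crossing or slope
  structures require a different tool.
* `fit_lmm` treats day as a linear fixed effect; strongly non-linear
  time-courses (late-stage collapse) need either a trajectory term or
  per-day testing.
* The pipeline consumes instrument *exports*; speckle tracking itself —
  image registration, contouring, tracking quality — is out of scope.
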