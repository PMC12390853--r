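---
title: "Methods: models, parameters and design choices in trimanus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in trimanus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimanus)
```

trimanus re-creates the software layer of a hybrid gaze–EEG–manual
("tri-manual") VR control system as an offline, fully seeded simulation:
synthetic multimodal streams in; activation events, control authority,
trial outcomes and metric tables out. This vignette documents the models,
the tunable parameters that matter, and the choices made where the design
was genuinely open. Nothing here states an empirical result that the test
suite does not itself compute.

## 1. The synthetic world

No real recordings ship with the package; every test runs against
generated sessions with known ground truth. The generators emulate the
*statistical structure the pipeline assumes*, not the physiology itself.

**EEG** (512 Hz, µV) is a pink-noise floor (SD 8 µV) plus three
band-limited oscillators — θ at 6 Hz (7 µV), α at 10 Hz (9 µV), β at 20 Hz
(5 µV) — each a sinusoid with a slow random phase walk so its power
occupies a realistic bandwidth. During an attention episode of level
L ∈ [0, 1], β amplitude scales by (1 + 2L) and α by (1 − 0.5L): a level-1.0
episode triples β amplitude and halves α power, a deliberately strong
"engaged" state. The default schedule is three 4-s episodes per 60-s
trial, well separated (onsets every 20 s). Blinks are 300 ms raised-cosine
deflections peaking at 150 µV; muscle bursts are 150 ms white-noise bursts
(SD 40 µV, rescaled if needed so some gradient exceeds 55 µV/sample) —
both exceed the detection thresholds by construction, and the generator
verifies this after superposition. Default artifact rates are 4 blinks and
1 muscle burst per minute. Spontaneous blink rates are higher at rest, but
blink suppression during visually demanding tasks is well documented, and
at ~10 artifacts/min the quality-reset rule (quality < 150 resets the
persistence timer) would keep the trigger disabled most of the time — not
a workable stated world for a system that is supposed to function.

**Gaze** (120 Hz, degrees of visual angle, head-fixed, (0,0) straight
ahead) is a fixation–saccade process over the scene targets: gamma
fixation durations (mean ≈ 0.35 s, clamped to [0.1, 1.5] s), 40 ms linear
saccades, observation noise N(0, 0.5²) per axis, 2% dropout in 100 ms
runs. No main-sequence saccade dynamics are modelled (a stated non-goal).

**Controller poses** (90 Hz, metres) rest at fixed home positions and move
along minimum-jerk profiles s(τ) = 10τ³ − 15τ⁴ + 6τ⁵, whose closed-form
peak speed 1.875·d/T anchors the generator tests.

What a green test establishes, therefore, is that the pipeline behaves
correctly *on signals with this structure*. It does not establish
classifier-grade performance on human EEG: real single-channel recordings
have non-stationary spectra, eye-movement leakage and electrode drift the
generator deliberately omits.

## 2. EEG pipeline

Processing follows the conventional single-channel chain: per-2-s-window
artifact screening (±100 µV amplitude, 50 µV/sample gradient, σ > 35 µV
contact check; each flag opens a 500 ms blanking interval), zero-phase
4th-order Butterworth band-pass 4–40 Hz, 500 ms moving-average detrend,
Welch PSD (256-point FFT, Hamming, 50% overlap), band powers by
rectangular integration over half-open bands [lo, hi) (so 8 Hz belongs to
α only), and the ratio β/(α + θ) normalised by a 30-s rolling mean. Frames
are emitted at 8 Hz from trailing 2-s windows; the 10 features are the
three band powers, their first-difference derivatives, the raw ratio, the
normalised attention, the quality index and the zero-crossing rate.

Numerical choices worth knowing:

* No IIR filter-design package exists in the target environment, so the
  Butterworth design (analog prototype → band-pass transform → bilinear
  transform) and forward–backward filtering are implemented here. The
  forward–backward pass seeds each direction with the step steady-state
  initial conditions; without them the 4 Hz pole's transient survives any
  reasonable reflection padding. The design is frozen against reference
  coefficients in the test suite, and the Welch estimator is checked
  against an independently coded periodogram average to 10⁻⁶ relative.
* The quality index is 200 × (1 − fraction of flagged 2-s windows in the
  trailing 10 s), clamped to [0, 200], **higher is better**. Consumer
  headsets report a 0–200 *poor-signal* index; the published usage
  ("below 150/100/50" disables things) only makes sense with
  higher-is-better, which is what is implemented.
* A frame is marked `blanked` when its trailing analysis window *touches*
  a blanking interval, not only when the frame time lies inside one: a
  frame 1.5 s after a muscle burst still summarises contaminated samples.
  The low-level `blanking_gate()` primitive retains the literal interval
  semantics.
* Attention is calibrated to the familiar 0–100 scale by the empirical
  CDF of the normalised ratio over the calibration run (the session
  itself, blanked frames excluded). The mapping between the vendor scale
  and the band-ratio metric is not published; the percentile form is
  chosen because personalised thresholds are in practice calibrated as the
  80th percentile of sustained attention — under the CDF mapping the
  default threshold of 80/100 *is* that percentile. Raw min–max mapping
  was rejected: it is dominated by single extreme frames.

Epoch bookkeeping uses 3.75-s epochs with 50% overlap starting every
1.875 s while the start lies inside the trial, the final epoch zero-padded
(count = ⌈duration/step⌉): 32 epochs per 60-s trial, 640 across 20 trials.

## 3. Trigger cascade

Three tiers plus two guards, all auditable per event:

1. **Temporal**: attention above the effective threshold for 300 ms
   continuously. On the 8 Hz clock this means the first frame at/after
   t₀ + 0.3 s with the run unbroken, i.e. 375 ms after run start; any
   below-threshold frame or quality < 150 resets the timer. One candidate
   per unbroken run.
2. **Quality scaling**: threshold ×1.2 for quality in [50, 100), disabled
   below 50.
3. **Context**: reject if the candidate's *physical* normalised attention
   deviates more than 2.5 SD from the trailing ≤60-s buffer (blanked
   frames excluded). The percentile-scaled value is not used here — its
   marginal is uniform by construction, which would make a σ rule
   vacuous. Buffers under 10 s, or with zero variance, pass with a
   `context_unchecked` audit flag (cold-start behaviour is otherwise
   undefined).
4. **Blanking guard**: candidates at blanked frames are rejected.
5. **Refractory**: 1 s dead time after each accepted event, preventing
   duplicate events from one sustained episode.

The tier-subset ("cascade dominance") property is tested with the quality
tier held fixed: ablating the quality tier changes the effective threshold
and therefore shifts candidate timestamps, so a literal subset relation
across that ablation is not well defined.

## 4. Gaze engine

The filter is a linear-Gaussian state-space model with constant-velocity
transition and position-only observation; per axis the process noise is
the discretised white-noise-acceleration form q·[[dt³/3, dt²/2],
[dt²/2, dt]] with q = 0.1², and observation noise r = 0.5² (degrees).
These are the minimal A/H consistent with "predict gaze targets" when
only the noise variances are given. The covariance update uses the Joseph
form and raises an error if PSD-ness is lost. Tests pin the filter to the
closed-form scalar Riccati fixed point, to a batch least-squares oracle on
a 10-step instance (10⁻⁸), and to innovation-consistency bounds on
model-generated data.

The "45° visual cone" is read as a 45° *half-angle* about the gaze ray
(boundary inclusive); a `half_angle` argument exposes the 22.5° full-angle
alternative. PD gaze stabilisation maps the calibrated damping range
0.65–0.85 (printed in units that are dimensionally inconsistent for
angular signals, so treated as unitless) onto ζ = c/0.65 ∈ [1.0, 1.31) of
a second-order tracker with ω = 4π rad/s: monotone step response at every
calibrated value, velocity variance decreasing in c. Gaze entropy uses an
8×8 fixation grid over a ±30° workspace (neither grid nor window is
published; these are fixed here and recorded).

## 5. Arbitration

Two-modality softmax w_m ∝ exp(a·ε_m + b·t_m) over {manual, virtual};
the generic "sum over modalities" is resolved to exactly these two. The
gains a = 4.0, b = 1.0 /s are config-exposed defaults chosen so that a
fully confident, 2-s-stable virtual channel reaches w ≈ 0.98 against a
resting manual channel — the published material constrains only the
domains ε ∈ [0,1], t ∈ [0,2] s, not the gains. ε_manual is
controller-tracking validity (1 when tracked), t_manual the capped
time-since-motion, mirroring the virtual channel. Spatial overlap within
10 cm forces manual override regardless of weights, and an exact 0.5 tie
resolves to manual — both expressions of manual priority. t_gaze is
implemented as dwell time on the locked target (the alternative,
time-since-lock, is noted as an open reading). Handover latency is
measured from the first tick at which a flip's preconditions held
continuously to the flip tick; the hardware latencies of the original
system (hundreds of ms end-to-end) are expressly not reproduced.

## 6. Workload model and adaptation

Exact GP regression with the Matérn-3/2 kernel
k(r) = σ²(1 + √3 r/ℓ)e^(−√3 r/ℓ) on standardised features
(normalised duration = completion time / nominal 60 s; variance of
15–22 Hz band power over 2-s sliding windows; gaze entropy).
Hyperparameters maximise the log marginal likelihood (L-BFGS-B on log
parameters, three restarts, jitter 10⁻⁸σ²); the predictive SD is the
latent one, so far from data it reverts to the prior σ. The intervention
trigger uses the posterior *mean* (the credible-bound alternative is
unspecified in the source and not taken). Above 68/100 the three
interventions engage (threshold ×1.2, v_max 0.4 m/s, stiffness 2.5 N/mm);
they release below 63 — a 5-point hysteresis band added because a bare
threshold would chatter at every tick near 68. Applying the same score
twice is idempotent by construction.

The complexity score C = 0.5 Δx + 0.3 H_g + 0.2 N_d mixes metres, nats
and counts; each term is therefore normalised to [0, 1] (Δx/1.8 m,
H_g/log 64, N_d/N_max) before weighting so C is comparable across scenes;
the raw mixture is available behind `normalized = FALSE`. The weights are
taken as printed constants; re-deriving them would require the original
pilot data.

## 7. Task world and metrics

A kinematic point-hand world at 90 Hz: manual spheres capture on contact
and track their controllers 1:1; the virtual hand engages at the first
accepted activation, seeks sphere 3 under proportional control
(gain 3 /s), captures at the sphere radius, and carries it to its
wireframe target, hard-capped at v_max every tick. "Stabilising force at
2.5 N/mm" is realised as an extra proportional pull (per-second gain equal
to the stiffness) since no mass model exists; it strictly tightens
terminal error in paired simulations. Success = all three spheres within
5 mm simultaneously for a continuous 1 s.

Metric conventions: spatial error is the **final** placement error per
sphere (mm); efficiency is 100·optimal/actual path length with the
optimal path the straight polyline through the hand's goal-change
waypoints — the ≤100% direction is forced by tabulated efficiencies below
100%; smoothness is the negated log dimensionless jerk
−log[(T⁵/L²)∫‖x⃛‖²dt] (higher = smoother, minimum-jerk optimal);
coordination is the peak mean-removed, SD-normalised cross-correlation of
manual and virtual speed profiles within ±2 s of lag.

## 8. Evaluation arithmetic

Percent change is direction-aware (higher-better: 100(t−b)/b;
lower-better: 100(b−t)/b, reported to 1 d.p.); paired effect size uses the
paired-design convention d = t/√n — the only convention consistent with
every printed (t, d) pair in the reference comparison table; cohort
comparisons gate a paired t-test vs Wilcoxon on Shapiro–Wilk normality of
the differences, with rank-biserial correlation in the nonparametric
branch and Bonferroni-adjusted α = 0.05/6 across the six planned metrics.
Degenerate zero-variance differences are reported as such rather than
producing infinite statistics silently. Of the tabulated effect sizes,
five are t-based and reproduce exactly; the sixth row is a Wilcoxon whose
printed rank-biserial value cannot be reconstructed from the printed W
alone and is not asserted.

## 9. Known limitations

* The EEG generator's band oscillators are stationary within state; real
  attention dynamics drift, and the percentile calibration would need a
  dedicated calibration run online.
* Episode-level detection rates are properties of the stated synthetic
  world (strong level-1.0 episodes, clean or lightly artifacted signal) —
  they say nothing about human single-channel decoding accuracy.
* The classifier stage of the original system (CSP + bidirectional LSTM)
  is out of scope: single-channel CSP is ill-posed and no weights are
  published. The activation cascade is the only trigger path implemented;
  `detect_activations()` is the pluggable seam where a classifier would
  attach.
* Hardware synchronisation, rendering, physics and the measured latency
  figures are not modelled; latency utilities measure the *simulated*
  trace only.
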