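# trimanus

Offline, reproducible simulation and analysis of **tri-manual control**:
two physically tracked hands plus a third, *virtual* hand that is aimed by
gaze and triggered by a single-channel EEG attention metric. The package
targets researchers in BCI / VR neuroengineering who want to study the
algorithmic layer of such hybrid systems — attention decoding, false-trigger
gating, gaze filtering, control arbitration, workload adaptation — without
headsets, eye trackers or EEG hardware: every input stream is synthesised
with known ground truth.

## What it computes

**Attention decoding.** Raw single-channel EEG (512 Hz, µV) is screened for
artifacts (|x| > 100 µV blink, >50 µV/sample gradient, window σ > 35 µV),
band-passed 4–40 Hz with a zero-phase 4th-order Butterworth filter,
detrended with a 500 ms moving average, and summarised by Welch's method
(256-point FFT, Hamming, 50% overlap) into θ (4–8 Hz), α (8–12 Hz) and
β (12–30 Hz) band powers. The attention metric is

> A = [β / (α + θ)] normalised by its 30-s rolling mean,

emitted inside a 10-dimensional feature frame at 8 Hz together with band
powers, their derivatives, a 0–200 quality index and the zero-crossing
rate, then calibrated onto a 0–100 scale by the empirical percentile of the
calibration run.

**False-trigger gating.** A virtual-hand activation requires A > 80 (0–100
scale) sustained for 300 ms (quality < 150 resets the timer), a
quality-scaled threshold (×1.2 below quality 100, disabled below 50),
contextual validation (reject |z| > 2.5 against a 60-s buffer), artifact
blanking, and a 1 s refractory period. Every event carries a tier-by-tier
audit trail.

**Gaze engine.** A constant-velocity Kalman filter (process noise 0.1²,
observation noise 0.5² per axis, degrees) smooths fixation–saccade gaze;
targets inside a 45° cone of the gaze ray are ranked by angular offset and
locked at accepted activations. Gaze entropy H\_g = −Σ p log p over an 8×8
fixation map feeds the workload model.

**Arbitration.** Control authority is the two-class softmax
w = exp(a·ε + b·t) / Σ exp(·) over {manual, virtual} (a = 4, b = 1/s),
with unconditional manual override whenever a tracked hand comes within
10 cm of the virtual hand.

**Workload adaptation.** A Matérn-3/2 Gaussian process maps (normalised
duration, 15–22 Hz β-power variance, gaze entropy) to a 0–100 workload
score; above 68/100 the system raises the confirmation threshold ×1.2,
caps the virtual hand at 0.4 m/s, and adds 2.5 N/mm stabilisation (released
below 63, hysteresis). Task complexity is C = 0.5 Δx̂ + 0.3 Ĥ\_g + 0.2 N̂\_d
with each term normalised to [0, 1].

**Task world & evaluation.** A kinematic three-sphere scene (0.40 m
equilateral triangle, 10 cm spheres); success = all spheres within 5 mm of
their wireframe targets for 1 s. Trial metrics: final spatial error (mm),
trajectory efficiency (= 100·optimal/actual path length), a negated
log-dimensionless-jerk smoothness score, and peak manual–virtual velocity
cross-correlation. Evaluation utilities provide direction-aware percent
changes, paired-design Cohen's d = t/√n, and normality-gated paired
tests with Bonferroni-adjusted α = 0.05/6.

## Worked example

```r
library(trimanus)
cfg <- session_config(seed = 1, trial_duration = 60, n_trials = 1)
td  <- simulate_trial(cfg)                    # EEG + gaze + poses + truth
fx  <- scale_attention(feature_stream(td$eeg))
ev  <- detect_activations(fx)
ev[, c("time", "attention", "quality", "z_context", "accepted")]
#>     time attention quality z_context accepted
#> 1 29.375  85.84071     160  1.892258     TRUE
#> 2 47.625  92.03540     160  2.758834    FALSE   # rejected: context tier
sc <- scene()
tr <- run_trial(sc, td$pose, ev, duration = 60)
trial_metrics(tr, sc$targets)
#> success: TRUE at 32.74 s | spatial error (mm): 0 0 0
#> efficiency: 100.0% | jerk score: -30.49
```

The first activation passes all tiers and engages the virtual hand, which
captures sphere 3 and carries it to its target; the second candidate
deviates 2.76σ from its 60-s attention buffer and is rejected by the
contextual tier. Printed-table consistency checks reproduce all tabulated
improvement percentages and effect sizes from their inputs:

```r
check_printed_table(read_metrics_table(
  system.file("extdata", "performance_comparison.tsv", package = "trimanus")))
#>             metric improvement_pct improvement_recomputed d_recomputed
#>    tasks_completed            65.6                   65.6         2.42
#>   spatial_error_mm            30.8                   30.8         1.81
#>         efficiency            21.1                   21.1         2.80
#>           nasa_tlx            25.8                   25.8           NA
#>       success_rate             7.7                    7.7         1.49
#>          precision            26.6                   26.6         2.00
```

## CLI

```sh
inst/exec/trimanus simulate --seed 3 --out /tmp/session
inst/exec/trimanus gate --in /tmp/session --out /tmp/session
inst/exec/trimanus report
```

See the methods vignette (`vignettes/trimanus-methods.Rmd`) for the model
assumptions, parameter choices and the limits of what the synthetic world
can establish.
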