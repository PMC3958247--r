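# fatiguetrack

Online tracking of muscular fatigue from wearable surface-EMG and
accelerometer recordings, for human-movement and exercise-physiology work
where per-muscle and whole-movement fatigue must be quantified without
invasive measurement.

## What it computes

A fatiguing muscle's sEMG power spectrum drifts towards low frequencies:
the spectral mean frequency (MNF, the PSD centroid) declines roughly
linearly with working time, `f_mean(t) = φ·t + ε`. **fatiguetrack**
estimates the MNF trajectory with a moving-window FFT, tracks its slope
online with forgetting-factor recursive least squares,

    φ̂_t = φ̂_{t-1} + p_{t-1}·t / (λ + t²·p_{t-1}) · (y_t − φ̂_{t-1}·t)
    p_t  = p_{t-1} / (λ + t²·p_{t-1})          (λ = 0.95 by default)

and reports the localized fatigue level `l_fatigue(t) = φ̂_t·t / f_mean,0`
(0 when fresh, negative under fatigue, shown in percent). Movement type is
decided from the accelerometer autocovariance: periodic
contraction–recovery work (`(Max₁ − Max₂)/Max₂ < ε` over the two largest
covariance peaks) has its active sEMG stretches segmented and concatenated
first; sustained holds are analyzed directly. Per-muscle levels are fused
into one overall level `L = Σ αᵢ·lᵢ` with convex weights proportional to
each level's gradient magnitude.

A fully seeded synthetic module (`gen_semg()`, `gen_acceleration()`,
`gen_session()`) generates sEMG-like band noise with a prescribed centroid
decline plus periodic or sustained acceleration traces, so the entire
pipeline is testable with known ground truth.

## Worked example

Simulate a one-minute three-muscle session (sustained hold; per-muscle MNF
slopes −0.25, −0.05, −0.20 Hz/s from 100 Hz; sensor rates 4000/296 Hz) and
run the full pipeline:

```r
library(fatiguetrack)
ses <- gen_session(seed = 1)
run <- run_pipeline(ses)
print(run)
#> <fatigue_run> 3 muscle(s), 985 fused step(s)
#>   biceps_brachii         sustained    final level  -12.7%  (F = 815.9, p = 3.76e-131)
#>   anterior_deltoid       sustained    final level   -4.3%  (F = 42.5, p = 1.12e-10)
#>   triceps_brachii        sustained    final level  -10.7%  (F = 324.9, p = 5.62e-63)
#>   overall final level: -10.1%
```

Each line shows the detected movement mode, the final localized fatigue
level, and the regression F-test that the linear decline is real (all
three muscles: p « 0.05). The fastest-fatiguing muscles (biceps, triceps)
dominate the overall −10.1% through the gradient weights, and the ranking
of final levels follows the ground-truth slopes. Periodicity detection on
a paced-lift trace:

```r
acc <- gen_acceleration(60, 296, "periodic", period = 2.5, snr = 20, seed = 2)$channel
detect_periodicity(cross_covariance(acc, 0.5), epsilon = 2)
#> <periodicity_result> periodic (ratio 0.054 < 2.000), period ~ 739 samples
```

739 samples at 296 Hz ≈ 2.50 s — the movement period. A command-line
interface wraps the same functions:

```sh
fatiguetrack simulate --out session/ --seed 1 --mode periodic
fatiguetrack run --in session/ --out results/
```

(installed under `exec/`; exit codes 0 = ok, 1 = input error,
2 = invariant violation).

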