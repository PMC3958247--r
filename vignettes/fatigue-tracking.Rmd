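---
title: "Tracking muscular fatigue from wearable sEMG and acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking muscular fatigue from wearable sEMG and acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguetrack)
```

## The problem

As a muscle fatigues, the power spectrum of its surface electromyogram
(sEMG) compresses towards lower frequencies: the spectral *mean frequency*
(MNF) — the centroid of the power spectral density — declines roughly
linearly with working time. **fatiguetrack** turns this observation into an
online fatigue monitor for wearable sensors. Each monitored muscle
contributes one sEMG channel (volts, kHz-range sampling) and a tri-axial
accelerometer (g, hundreds of Hz). The pipeline produces, per muscle, a
*localized fatigue level*

$$ l_{\mathrm{fatigue}}(t) \;=\; \frac{f_{\mathrm{mean}}(t)}{f_{\mathrm{mean},0}} - 1 $$

(the relative MNF decrease from its initial value; 0 when fresh, negative
under fatigue, reported in percent), and one *overall* fatigue level
$L_{\mathrm{fatigue}}(t) = \sum_i \alpha_i\, l_{\mathrm{fatigue},i}(t)$
with convex, gradient-normalized weights $\alpha_i$.

Two working patterns need different handling. During a *sustained*
contraction (e.g. holding one's own body weight) the sEMG is continuously
active and can be analyzed as-is. During *periodic* contraction–recovery
work (e.g. paced arm curls, one lift every ~2.5 s) only the contraction
phase carries signal; the recovery gaps would dilute the spectral
estimate, so the active stretches are segmented out and concatenated
first. The movement pattern is decided automatically from the
accelerometer.

## Pipeline

`run_pipeline()` executes, per muscle:

1. **Pre-filter** sEMG and acceleration with minimal-order Butterworth
   low-passes (`design_butterworth()`, `apply_filter()`).
2. **Resample** the sEMG onto the (lower) accelerometer rate and truncate
   to a common length (`resample_to_common()`).
3. **Detect periodicity** from the lagged autocovariance of the
   acceleration (`cross_covariance()`, `detect_periodicity()`).
4. If periodic: **segment and connect** the active sEMG
   (`segment_and_connect()`); otherwise skip.
5. **Mean-frequency trajectory** by moving-window FFT centroid
   (`mean_frequency_series()`), including the initial reference
   $f_{\mathrm{mean},0}$.
6. **Track the slope** with forgetting-factor recursive least squares and
   convert to the localized level (`track_fatigue()`).
7. **Diagnose linearity** with the regression F-test
   (`linearity_ftest()`).
8. **Fuse** muscles with per-step gradient weights into the overall level.

Every decision (periodicity ratio, segment count, F statistic, final
levels) is logged in the run report (`write_run_report()`).

## Parameters and their defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `semg_filter` | Wp 0.1, Ws 0.4, Rp 3, Rs 40 | Nyquist fraction, dB | sEMG low-pass corners (200/800 Hz at 4 kHz) |
| `acc_filter` | Wp 0.003, Ws 0.006 | Nyquist fraction | acceleration low-pass (~0.44/0.89 Hz at 296 Hz) |
| `window_length` / `window_overlap` | 0.125 / 0.063 | s | moving-window spectral estimation |
| `lambda` | 0.95 | — | forgetting factor; memory $\approx 1/(1-\lambda)$ = 20 windows |
| `phi0`, `p0` | 0, 10000 | — | initial slope estimate and gain state |
| `epsilon` | 2 | — | periodicity threshold on the peak ratio |
| `max_lag_fraction` | 0.5 | — | covariance lag cap (fraction of record) |
| `peak_prominence` | 0.25 | fraction of $\phi(0)$ | covariance peak prominence floor |
| `f0_windows` | 5 | windows | windows averaged into $f_{\mathrm{mean},0}$ |
| `smoothing_window` | 9 | samples | level smoothing before fusion gradients |

The filter corners are interpreted as normalized fractions of Nyquist: at
the reference rates a literal reading in Hz would place the sEMG passband
edge at 0.1 Hz and annihilate all muscle content, whereas the normalized
reading (≈200 Hz at 4 kHz sampling) matches sEMG practice. Sampling rates
are always taken from channel metadata, never hard-coded.

## The tracking model

With the linear MNF model $f_{\mathrm{mean}}(t) = \varphi t + \varepsilon$,
the slope $\varphi$ is tracked by scalar exponentially-weighted recursive
least squares:

$$ \hat\varphi_t = \hat\varphi_{t-1}
   + \frac{p_{t-1} t}{\lambda + t^2 p_{t-1}}
     \left(y_t - \hat\varphi_{t-1} t\right), \qquad
   p_t = \frac{p_{t-1}}{\lambda + t^2 p_{t-1}}. $$

At $\lambda = 1$ this recursion is exactly batch through-origin least
squares (given a large prior $p_0$); at $\lambda = 0$ it keeps only the
current sample and $p_t = t^{-2}$; in between it is a restricted Kalman
filter whose responsiveness to slope changes grows as $\lambda$ falls.

**The residual term.** A through-origin regressor cannot represent a
~100 Hz spectral baseline at $t = 0$. We therefore regress the *de-meaned*
ordinate $y_t = f_{\mathrm{mean}}(t) - f_{\mathrm{mean},0}$ on $t$, so the
baseline is absorbed as the model intercept, and evaluate the level as
$l(t) = \hat\varphi_t\, t / f_{\mathrm{mean},0}$. This is the only reading
under which $l(0) = 0$ (a fresh muscle is unfatigued) and the level is
invariant to rescaling the whole series. The literal through-origin form
remains available via `demean_regression = FALSE` for comparison.

**Time variable.** Seconds for continuous records; for connected
(segmented) records the concatenated axis is no longer physical time, so
the window index is used instead. Levels from the two modes are therefore
comparable as fractions, not as rates.

**Initial reference.** $f_{\mathrm{mean},0}$ defaults to the mean of the
first 5 windows (`f0_windows = 1` restores the literal single-window
definition). One 0.125 s window has a centroid standard deviation of
several Hz, and any error $e_0$ in the reference propagates into the
tracked slope as $-e_0/t$ — at 60 s this term, not the RLS noise,
dominates the slope uncertainty (about 0.05 Hz/s standard deviation under
the synthetic conditions below). Slopes are therefore recovered *reliably
in sign and order of magnitude*, with relative accuracy that improves with
record length and with steeper declines.

## Periodicity detection

The acceleration autocovariance
$\phi(m) = \sum_n (x_{n+m}-\mu)(x_n-\mu)$ (biased, mean-removed,
un-normalized; lags capped at 50% of the record) repeats for periodic
movement, so its peak at one period rivals the lag-0 peak. The decision
rule declares periodic movement when the two largest local peaks satisfy
$(\mathrm{Max}_1 - \mathrm{Max}_2)/\mathrm{Max}_2 < \epsilon$ with
$\epsilon = 2$; the period estimate is the lag of the strongest positive
peak, and the decision is scale-free.

Peaks are qualified by **topographic prominence** (height above the higher
flanking valley), not raw value, with a floor of 0.25 times $\phi(0)$.
Both choices matter in practice. Measurement noise riding on the slowly
decaying covariance of a sustained hold creates shallow wiggles whose
*values* are close to $\phi(0)$ — a value floor admits them and
misclassifies sustained work as periodic. With the near-DC acceleration
low-pass, residual noise wander can still produce bumps with prominence up
to ~0.15 of $\phi(0)$, while genuine periodic second peaks exceed 1.0 of
$\phi(0)$ (the covariance dips negative between cycles): the 0.25 floor
splits the two populations with a wide margin on each side. Tri-axial
input is reduced to the axis of largest variance by default
(`axis_select = "magnitude"` uses the Euclidean norm instead).

Zero-phase filtering pads the record by odd reflection over ~10 time
constants of the slowest filter pole before the forward–backward pass.
Without this, the order-7 near-DC acceleration filter rings at the record
edges at roughly its cutoff frequency, and the ringing itself looks
periodic to the covariance analysis.

## Segmentation of periodic sEMG

Active samples are located on the centered moving power (window =
`window_length`, double-smoothed: short-window power of band-limited
noise has only ~5 independent samples and ~45% relative scatter). The
threshold is the midpoint between the rest and contraction power
plateaus — estimated as class medians iterated from a decile split, since
tail means overestimate the loud plateau badly under that scatter. The
midpoint rule has a geometric virtue: a centered window straddling a hard
burst edge holds exactly half the burst power, so the threshold crossing
falls on the edge itself and burst lengths are recovered to within one
window. The binary mask is then cleaned by closing gaps and dropping
islands shorter than one window. Records with no rest phase (loud/quiet
power ratio below `activity_k`² = 9) are treated as fully active rather
than force-split. Period breakpoints, anchored at the global acceleration
extremum, are kept in the `segment_map` for audit, and intervals serialize
as 0-based half-open sample ranges.

## Spectral estimation choices

`psd_window()` computes the one-sided $|\mathrm{FFT}|^2$ periodogram,
scaled so it integrates to the segment's mean square (Parseval). A Hann
taper (power-compensated) is the default for 0.125 s windows, where
leakage is the main worry; `taper = "rectangular"` gives the raw
periodogram. The centroid uses trapezoidal quadrature on the discrete
grid, DC bin included; rectangle-rule and trapezoid centroids agree to
within one bin. Window stepping is rounded to integer samples and a final
partial window is dropped, so window counts are reproducible. The
spectral centroid is a ratio estimator, so with few effective bins it
carries a small positive (Jensen) bias — fractions of a Hz at the default
settings — which cancels in the de-meaned slope regression.

## Fusion

Weights follow the normalized gradient magnitudes of the (smoothed)
localized levels: muscles whose fatigue is changing fastest dominate the
overall level. Because the system is an online tracker, weights are causal
by default — trailing moving average (window 9) and backward difference
using only levels seen so far; `causal_weights = FALSE` switches to
whole-record centered gradients for offline analysis. Where every gradient
vanishes (including the first step) the weights fall back to uniform
$1/N_m$, the symmetric completion of an otherwise 0/0 expression. Fixed
expert weights can be supplied via `fusion_weights`. The fused level is a
checked convex combination: weights must be non-negative and sum to 1
within $10^{-9}$, and the result always lies inside the envelope of the
localized levels.

## The synthetic module

Because no recordings ship with the package, `gen_semg()`,
`gen_acceleration()` and `gen_session()` generate every input with known
ground truth, fully determined by a seed.

* **sEMG**: white Gaussian noise shaped in half-overlapping 0.25 s blocks
  (square-root-Hann crossfades, constant expected power) by a
  frequency-domain band filter — flat top of width 40 Hz with
  raised-cosine edges, symmetric about the prescribed centroid
  $f(t) = f_0 + \mathrm{slope}\cdot t$ — so the instantaneous spectral
  centroid equals $f(t)$ analytically. (A Butterworth band-pass was
  rejected here: its geometric frequency symmetry biases the realized
  centroid slope by ~5%.) Broadband measurement noise is added at the
  requested SNR; it shifts the mixture centroid slightly towards
  mid-Nyquist, a property of any additive-noise spectrum.
* **Acceleration**: a smooth fundamental-plus-second-harmonic waveform for
  periodic lifts (default period 2.5 s), or an exponential posture settle
  with a mild trend for sustained holds; plus white noise at the given
  SNR. Default rates mirror the reference hardware (4000 Hz sEMG, 296 Hz
  acceleration).
* **Sessions**: a three-muscle roster (biceps brachii, anterior deltoid,
  triceps brachii) with distinct slopes (−0.25, −0.05, −0.20 Hz/s from
  100 Hz). In periodic mode the sEMG is gated to the contraction phase of
  each cycle with brief (5%) Tukey ramps, so true active intervals are
  known; accelerometer axis 1 carries the movement, axes 2–3 attenuated
  crosstalk plus noise.

What the generator does *not* emulate — and what passing tests therefore
cannot certify on real data: motor-unit action-potential shapes and firing
statistics, electrode-contact and motion artifacts, amplitude
nonstationarity beyond burst gating, heteroscedastic or non-Gaussian
noise, inter-muscle crosstalk in the sEMG, or deviations from a linear MNF
decline. The generator verifies the *computation*, not the physiology.

## Numerical conventions and degenerate inputs

* Covariance via zero-padded FFT; agrees with the direct $O(N^2)$ sum to
  ~1e−12 relative. A constant signal gives an all-zero series, which is
  handled (non-periodic), as are single-peak covariances and a
  non-positive second peak (division guard in the decision ratio).
* Peak ties are broken towards the smaller lag; window steps and RMS
  windows are forced to integer (odd) sample counts — all for determinism.
* The RLS gain denominators $\lambda + t^2 p$ are positive whenever
  $p > 0$; positivity of $p$ is asserted at every step. Non-increasing
  time stamps raise a sequencing error.
* A numerically perfect regression fit reports $F = \infty$, $p = 0$.
* All-zero spectra raise an undefined-mean error rather than returning 0.
* Smoothing windows must be odd; edges shrink symmetrically so no phase is
  introduced.

## Problem sizes used by the test-suite

Unit tests run on 1–60 s records at 250–4000 Hz; Monte-Carlo checks use
100 seeds (classification, slope recovery) or 2000 draws (F-test size);
end-to-end sessions use 30 s three-muscle recordings at 1184/296 Hz — an
exact 4:1 polyphase ratio — with one full-rate 4000/296 Hz default-session
check. These sizes are the package's chosen verification conditions; the
code itself has no special-case behavior at any of them.

## Known limitations

* The linear MNF model is an approximation; strongly nonlinear declines
  (e.g. near task failure) are summarized by their current local slope.
* Slope estimates inherit the variance floor discussed above; short
  records with shallow declines give noisy levels, and the per-muscle
  F-test in the run report is the intended guard against over-reading
  them.
* The periodicity rule assumes a single dominant movement period; mixed or
  multi-harmonic movement (gait-like patterns) is out of scope.
* Fusion aligns trajectories by step index after truncation to the
  shortest; mixing periodic and sustained muscles in one session is
  flagged in the report but the fused axis is then an index, not seconds.
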