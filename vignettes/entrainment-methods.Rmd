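---
title: "Methods: tremor frequency estimation and the cued-entrainment session engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tremor frequency estimation and the cued-entrainment session engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainr)
```

## The therapy model

Functional tremor entrains to externally cued voluntary movement: asking the
patient to move the wrist in time with a rhythm at a frequency different
from the tremor's own tends to pull the tremor to that rhythm or suppress
it. The session engine implemented here turns that diagnostic observation
into a treatment protocol:

1. **Baseline** — the first 10 s of a session measure the dominant tremor
   frequency $f_0$ from the wrist accelerometer.
2. **Phase 1** — auditory cues at $\tfrac{2}{3} f_0$ for half of the
   remaining session time.
3. **Phase 2** — cues at $\tfrac{1}{3} f_0$ for the other half.

Throughout, the patient's *voluntary* movement frequency is tracked and fed
back on a gauge centred on the current cue frequency. The programme runs
seven days: a 60-minute supervised session on day 1, 30-minute at-home
sessions on days 2–7, each logged with the duration completed.

"Half a session" is implemented as half of the *post-baseline* treatment
time: cues can only exist once $f_0$ is known, so the 10-s baseline is
excluded from both halves and the treatment time is split exactly equally.
Phase intervals are half-open, $[t_\text{start}, t_\text{end})$, so every
elapsed time belongs to exactly one phase and a cue landing exactly on a
boundary belongs to the next phase.

## Spectral estimation

The three axes are reduced to one zero-mean series before any spectral
step. The default reduction is the per-sample Euclidean **magnitude** with
the series mean removed: it is orientation-independent and removes the
constant gravity component. One caveat, deliberately exercised by the
simulator: if the oscillation is exactly orthogonal to gravity, the
magnitude responds only quadratically and the spectrum shows $2 f_0$
instead of $f_0$ (rectification). Real wrist flexion–extension always has a
component along gravity, and the simulator's default axis weights place
part of the oscillation on the gravity axis for the same reason. The
alternative `dominant_axis` reduction (highest-variance axis) is offered
for comparison; whether the magnitude, a single axis, or all three axes
should be considered canonical is left open, and neither choice is asserted
as "the" deployed behaviour.

The dominant frequency is the argmax of a Hann-tapered power spectrum,
zero-padded so the frequency grid is at most 0.1 Hz apart, restricted to
the physiological tremor band 1–12 Hz. The 0.1 Hz ceiling keeps the induced
cue-frequency error below $\tfrac{2}{3}\times 0.1 = 0.07$ Hz. Argmax ties
resolve to the lowest frequency, making the estimator deterministic.

**Baseline averaging.** The 10-s baseline uses a Welch-style average of
Hann periodograms over 50 %-overlapping sub-windows of 40 % of the baseline
(4 s sub-windows, four segments at the defaults) on a common zero-padded
grid. Averaging reduces the variance of the noise floor considerably, which
is what makes the no-tremor fallback decision reliable; if the
sub-windows would be too short to hold two cycles of the lower band edge,
one full-prefix periodogram is used instead.

**Peak significance.** A peak counts as tremor only if its power is at
least `prominence_factor` times the *median* in-band power. The default
factor is 20, calibrated on the null distribution: the peak-to-median
ratio of a pure-noise Hann periodogram in the 1–12 Hz band ranges to about
17 across 3–10-s windows (measured over 300 seeded draws), whereas a
sinusoid at a signal-to-noise ratio of 1 or better scores at least 67.
Twenty therefore separates the two regimes with margin on both sides. When
the baseline peak fails this criterion the session uses the fallback
`f_default` = 4.5 Hz — chosen so that the clamped phase frequencies (3.0
and 1.5 Hz) sit strictly inside the clamps — and the session is flagged as
having run without detectable tremor.

**Tracking.** The voluntary movement frequency is re-estimated in sliding
3-s windows advanced by 0.5 s: three cycles of the 1 Hz band floor per
window, responsive enough for a live gauge. Windows that fail the
prominence criterion are reported as `NA` rather than a number, and the
gauge pegs them at the low rail so absent movement is visible.

## Protocol constants

| parameter | default | meaning |
|---|---|---|
| `baseline_duration` | 10 s | tremor measurement before the first cue |
| `ratio_phase1`, `ratio_phase2` | 2/3, 1/3 | cue-to-baseline frequency ratios |
| `f_min`, `f_max` | 1, 5 Hz | treatment-frequency clamps |
| `f_default` | 4.5 Hz | baseline fallback without detectable tremor |
| `day1_duration`, `daily_duration` | 3600, 1800 s | session lengths |
| `band_low`, `band_high` | 1, 12 Hz | tremor search band |
| `goal_tolerance` | 0.10 | goal-range half-width (fraction of cue) |
| `half_scale` | 0.5 | relative error at full gauge deflection |
| `prominence_factor` | 20 | peak-significance multiple of median power |
| `window_length`, `hop` | 3, 0.5 s | tracker window geometry |

The clamps' values are not fixed by the protocol itself; 1 Hz is the floor
below which cued movement stops being rhythmic wrist flexion–extension, and
5 Hz caps sustained voluntary wrist oscillation at a tolerable rate. They
also make the engine well-defined on a tremor-free start (via `f_default`).
Any uniform sampling rate of 25 Hz or more is accepted; irregular streams
are rejected rather than resampled.

## The gauge

The needle is linear in the *relative* frequency error,
$\mathrm{needle} = \mathrm{clip}\!\big((f_m - f_\text{cue}) / (h \cdot
f_\text{cue}), -1, +1\big)$ with $h$ = `half_scale`. Normalising by the
cue frequency makes the gauge equally sensitive at a 1.5 Hz and a 4 Hz
goal; the needle is exactly zero when the measured frequency equals the
cue frequency, for any cue frequency, and the goal range (±10 % of the
cue, roughly one tracker bin at the defaults) is centred on the dial.

## The simulator

`simulate_tremor()` generates
$a\,[\sin\phi(t) + r_h \sin 2\phi(t)]$ with $\phi' = 2\pi f(t)$,
$f(t) = f_\text{tremor} + \dot f\, t/60$, distributed over the axes by a
unit weight vector, plus gravity on one axis and i.i.d. Gaussian sensor
noise per axis; everything is reproducible from the scenario seed.
`simulate_entrained_subject()` adds the simplest cue-following mechanism
that exhibits both an "entrains" and a "fails to entrain" regime: the
instantaneous movement frequency relaxes exponentially (time constant
`tracking_lag`, default 1 s) towards the convex combination
$\rho f_\text{cue} + (1-\rho) f_\text{tremor}$ with responsiveness
$\rho \in [0,1]$, plus Gaussian frequency jitter low-pass filtered at
0.5 Hz (and rescaled to the requested standard deviation) so tracker
windows remain quasi-stationary. Jitter is applied in frequency, not
phase.

What the simulator does **not** emulate: biomechanical wrist dynamics,
tremor amplitude fluctuation or intermittency, orientation changes of the
device during a session, sensor dropouts, and the coexistence of tremor
*and* voluntary movement as separate spectral components — the entrained
subject replaces one with the other. Tests passing on these simulations
therefore validate the engine's logic and its statistical behaviour under
stationary oscillation plus white noise; they do not establish performance
on recordings from patients.

Default study conditions used by the simulator and the verification runs:
50 Hz sampling, oscillation amplitude 1 m/s², sensor noise 0.1 m/s²
(0.5 m/s², i.e. half the amplitude, in the noisy-recovery runs),
responsiveness 1, lag 1 s, jitter 0.05 Hz. Verification problem sizes:
10-s recordings for estimator accuracy (a 7-point frequency grid, plus 100
noisy replicates), full 1800-s day-2 sessions for the end-to-end
cue-following runs, and 25–50 random configurations per invariant suite.

## Numerical choices and degenerate inputs

* FFT length: the series is zero-padded to the next power of two at or
  above $\max(n, f_s/0.1)$; the brute-force $O(n^2)$ DFT used as a test
  oracle evaluates the identical grid, window and power definition.
* Time grids must be strictly increasing and uniform within $10^{-6}$ s;
  recordings are written with nine decimals so a write–load round trip is
  exact to $10^{-9}$.
* Completion is resolved at sample precision: a recording within half a
  sample period of the scheduled duration counts as complete; shorter
  recordings are truncated, never extrapolated.
* A session restart is a new session; one log entry per protocol day is
  enforced, and adherence is duration-weighted (completed seconds over
  scheduled seconds — the natural reading when reported percentages are
  not multiples of one sixth), with missing days counting as zero
  completed over their full scheduled duration.
* Zero-length phases produce no cues; an empty frequency trace produces an
  empty gauge trace.

## Limitations

The engine is an offline replay of the session logic: it does not capture
audio, render the dial, or run in real time. Baseline frequency is
estimated once per session and never re-estimated mid-session. All
performance figures quoted anywhere in this package are computed by the
test suite or by `scripts/acceptance.R` on simulated recordings under the
conditions above.
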