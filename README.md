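# entrainr

Offline engine for entrainment-based retraining of functional tremor.

Functional tremor entrains: when a patient deliberately moves a limb in time
with an external rhythm, the tremor tends to adopt that rhythm or abate.
`entrainr` implements the computational core of a cued-entrainment therapy
session around a wrist accelerometer: it measures the dominant tremor
frequency, schedules auditory cues at a *lower* frequency for the patient to
match with wrist flexion–extension movements, tracks the voluntary movement
frequency continuously, and scores it on a bounded biofeedback gauge. A
tremor/subject simulator makes the whole pipeline testable without hardware.
It is aimed at researchers and engineers working on movement-disorder
digital therapeutics who need a reproducible, scriptable reference of the
session logic.

## The method

Given a 3-axis accelerometer recording (t, x, y, z; m/s²), the three axes
are reduced to one zero-mean oscillation series (Euclidean magnitude or the
highest-variance axis). The **baseline tremor frequency** f₀ is the peak of
a Welch-style averaged, Hann-tapered, zero-padded power spectrum of the
first 10 s of a session, searched in the 1–12 Hz band at ≤ 0.1 Hz grid
spacing; a peak below 20× the median in-band power is treated as "no
detectable tremor" and replaced by a flagged fallback frequency.

Each session of the seven-day programme (day 1: 60 min; days 2–7: 30 min)
then splits its post-baseline time into two equal halves with cue
(treatment) frequencies

    f_cue(phase 1) = clamp(2/3 · f₀, f_min, f_max)
    f_cue(phase 2) = clamp(1/3 · f₀, f_min, f_max)

with clamps (defaults 1–5 Hz) that keep sessions tolerable and well-defined
when no tremor is detected. Cue ("tick") times repeat at 1/f_cue from each
phase start. The voluntary movement frequency f_m(t) is tracked in sliding
3-s windows (0.5-s hop) and mapped to a gauge needle

    needle = clip( (f_m − f_cue) / (half_scale · f_cue), −1, +1 ),

which is exactly 0 when the user matches the cue, with a goal range of
±10 % of f_cue in the middle of the dial. Sessions are persisted as
JSON-lines log entries; adherence is duration-weighted (completed seconds /
scheduled seconds), per day and aggregated over the at-home days 2–7.

## Worked example

```r
library(entrainr)

cfg <- protocol_config()                       # published protocol constants
rec <- simulate_tremor(simulation_scenario(f_tremor = 6, duration = 12, seed = 1))
base <- compute_baseline(rec, cfg)
base$baseline_frequency
#> [1] 5.957031
plan <- build_phase_plan(2, base$baseline_frequency, base$significant, cfg)
plan
#> <phase_plan> day 2: baseline 0-10 s, phase 1 @ 3.971 Hz to 905 s,
#>              phase 2 @ 1.986 Hz to 1800 s

# a fully responsive simulated subject follows the cues through a 30-min session
sc  <- simulation_scenario(f_tremor = 6, duration = 1800, responsiveness = 1,
                           tracking_lag = 1, jitter_sd = 0.05, seed = 1)
res <- run_session(simulate_entrained_subject(sc, plan), 2, cfg)
res
#> <session_result> day 2: baseline 6.055 Hz, completed 1800/1800 s
g2 <- res$gauge[res$gauge$phase == "phase2", ]
median(g2$measured, na.rm = TRUE)              # phase-2 goal is f0/3
#> [1] 1.953125
mean(g2$in_goal)
#> [1] 0.9977616
```

The baseline estimate sits within one frequency bin (0.098 Hz) of the true
6 Hz tremor; the phase frequencies are 2/3 and 1/3 of it (clamped to
1–5 Hz); and during phase 2 the simulated subject's tracked movement
frequency stays in the ±10 % goal range in 99.8 % of windows.

A command-line wrapper is installed at
`system.file("cli", "entrainr", package = "entrainr")` with subcommands
`analyze`, `simulate`, `session`, and `report`; each prints one JSON object
on stdout and honours `--config`, `--seed`, `--band LO:HI`, `--day N`,
`--log` and `--out` (flags override config-file values). Example
configuration files are in `inst/extdata/`.

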