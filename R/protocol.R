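#' Protocol configuration
#'
#' All constants of the seven-day cued-entrainment protocol in one validated
#' object. Defaults encode the published protocol (10-s baseline, cue at 2/3
#' then 1/3 of the baseline tremor frequency, 60-min day-1 session, 30-min
#' sessions on days 2-7) plus this implementation's declared choices for the
#' constants the protocol leaves open (clamps, fallback frequency, analysis
#' band, tracker and gauge settings).
#'
#' @param baseline_duration Seconds of the session devoted to baseline tremor
#'   measurement before any cue (default 10).
#' @param ratio_phase1,ratio_phase2 Cue-to-baseline frequency ratios for the
#'   two treatment phases (defaults 2/3 and 1/3); must satisfy
#'   `0 < ratio_phase2 < ratio_phase1 < 1`.
#' @param f_min,f_max Treatment-frequency clamps in Hz (defaults 1 and 5 Hz):
#'   every cue frequency is forced into `[f_min, f_max]` for tolerability and
#'   to cope with tremor-free starts.
#' @param f_default Baseline frequency assumed, and flagged, when no
#'   significant tremor peak is found (default 4.5 Hz, so the clamped phase
#'   frequencies 3 and 1.5 Hz lie strictly inside the clamps).
#' @param day1_duration,daily_duration Scheduled session lengths in seconds:
#'   day 1 (default 3600 s) and days 2 onward (default 1800 s).
#' @param n_days Number of protocol days (default 7).
#' @param band_low,band_high Tremor search band in Hz (defaults 1-12 Hz).
#' @param goal_tolerance Half-width of the gauge goal range as a fraction of
#'   the goal frequency (default 0.10).
#' @param prominence_factor Spectral peak-significance threshold: the in-band
#'   peak must reach this multiple of the median in-band power (default 20,
#'   above the null range of a noise periodogram's peak-to-median ratio).
#' @param half_scale Gauge full-deflection point as a fraction of the goal
#'   frequency (default 0.5).
#' @param window_length,hop Frequency-tracker window and hop in seconds
#'   (defaults 3 and 0.5).
#' @param min_resolution Frequency-grid spacing ceiling in Hz (default 0.1).
#' @return An object of class `protocol_config` (a named list).
#' @export
protocol_config <- function(baseline_duration = 10,
                            ratio_phase1 = 2 / 3, ratio_phase2 = 1 / 3,
                            f_min = 1, f_max = 5, f_default = 4.5,
                            day1_duration = 3600, daily_duration = 1800,
                            n_days = 7,
                            band_low = 1, band_high = 12,
                            goal_tolerance = 0.10, prominence_factor = 20,
                            half_scale = 0.5,
                            window_length = 3, hop = 0.5,
                            min_resolution = 0.1) {
  cfg <- list(baseline_duration = baseline_duration,
              ratio_phase1 = ratio_phase1, ratio_phase2 = ratio_phase2,
              f_min = f_min, f_max = f_max, f_default = f_default,
              day1_duration = day1_duration, daily_duration = daily_duration,
              n_days = as.integer(n_days),
              band_low = band_low, band_high = band_high,
              goal_tolerance = goal_tolerance,
              prominence_factor = prominence_factor,
              half_scale = half_scale,
              window_length = window_length, hop = hop,
              min_resolution = min_resolution)
  if (any(!vapply(cfg, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all configuration values must be single finite numbers", call. = FALSE)
  if (!(0 < ratio_phase2 && ratio_phase2 < ratio_phase1 && ratio_phase1 < 1))
    stop("need 0 < ratio_phase2 < ratio_phase1 < 1", call. = FALSE)
  if (!(0 < f_min && f_min < f_max))
    stop("need 0 < f_min < f_max", call. = FALSE)
  if (baseline_duration <= 0 ||
      baseline_duration >= min(day1_duration, daily_duration))
    stop("baseline_duration must be positive and shorter than every session",
         call. = FALSE)
  if (!(goal_tolerance > 0 && goal_tolerance < 1))
    stop("goal_tolerance must be in (0, 1)", call. = FALSE)
  if (goal_tolerance >= half_scale)
    stop("goal_tolerance must be smaller than half_scale", call. = FALSE)
  if (!(band_low > 0 && band_low < band_high))
    stop("need 0 < band_low < band_high", call. = FALSE)
  if (cfg$n_days < 1L) stop("n_days must be at least 1", call. = FALSE)
  structure(cfg, class = "protocol_config")
}

#' Read a protocol configuration from a key-value file
#'
#' Flat text format, one `key = value` per line; `#` starts a comment and
#' blank lines are ignored. Keys must be [protocol_config()] argument names;
#' unknown keys are rejected. Unspecified keys keep their defaults.
#'
#' @param path Path to the config file.
#' @return A `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  do.call(protocol_config, read_keyvalue(path, names(formals(protocol_config))))
}

# Shared key=value reader for config and scenario files.
read_keyvalue <- function(path, allowed_keys) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed line (expected 'key = value'): ", lines[i], call. = FALSE)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% allowed_keys)
      stop("unknown key: ", key, call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Scheduled session duration for a protocol day
#'
#' Day 1 is the long, supervised session; every later day uses the shorter
#' at-home duration.
#'
#' @param day Protocol day, `1..cfg$n_days`.
#' @param cfg A [protocol_config()].
#' @return Duration in seconds.
#' @export
scheduled_duration <- function(day, cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  if (length(day) != 1L || day != as.integer(day) || day < 1 || day > cfg$n_days)
    stop("day must be an integer in 1..", cfg$n_days, call. = FALSE)
  if (day == 1) cfg$day1_duration else cfg$daily_duration
}

#' Baseline tremor frequency from the opening seconds of a session
#'
#' Averages Hann-tapered periodograms of 50%-overlapping sub-windows of the
#' first `cfg$baseline_duration` seconds (Welch-style) on a common
#' zero-padded grid and takes the in-band peak. When the peak fails the
#' prominence criterion — no detectable tremor — the configured fallback
#' `cfg$f_default` is returned with `significant = FALSE`.
#'
#' @param rec An [accel_recording] covering at least `cfg$baseline_duration`
#'   seconds.
#' @param cfg A [protocol_config()].
#' @param method Axis-combination rule passed to [combine_axes()].
#' @return List with `baseline_frequency` (Hz) and `significant` (logical).
#' @export
compute_baseline <- function(rec, cfg = protocol_config(),
                             method = c("magnitude", "dominant_axis")) {
  stopifnot(inherits(rec, "accel_recording"), inherits(cfg, "protocol_config"))
  if (recording_duration(rec) < cfg$baseline_duration)
    stop("recording shorter than baseline_duration (", cfg$baseline_duration,
         " s)", call. = FALSE)
  fs <- rec$sample_rate
  n_base <- round(cfg$baseline_duration * fs)
  series <- combine_axes(rec, match.arg(method))[seq_len(n_base)]
  # Welch segments: 40% of the baseline, 50% overlap -> 4 segments at the
  # default 10 s. Fall back to one full window if segments would violate the
  # two-cycles-of-band_low precondition.
  seg_len <- round(0.4 * n_base)
  if (seg_len < 2 * fs / cfg$band_low) seg_len <- n_base
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n_base - seg_len + 1L, by = step)
  spectra <- lapply(starts, function(s)
    tapered_power_spectrum(series[s:(s + seg_len - 1L)], fs, cfg$min_resolution))
  freq <- spectra[[1]]$frequency
  power <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
  in_band <- freq >= cfg$band_low & freq <= cfg$band_high
  fb <- freq[in_band]; pb <- power[in_band]
  k <- which.max(pb)
  significant <- pb[k] >= cfg$prominence_factor * stats::median(pb)
  list(baseline_frequency = if (significant) fb[k] else cfg$f_default,
       significant = significant)
}

#' Cue (treatment) frequency for a phase
#'
#' The raw cue frequency is the phase ratio times the baseline frequency;
#' the result is clamped into `[cfg$f_min, cfg$f_max]` so sessions remain
#' tolerable and well-defined even when the baseline estimate is extreme or
#' a fallback.
#'
#' @param f0 Baseline tremor frequency in Hz, positive.
#' @param phase `"phase1"` or `"phase2"`.
#' @param cfg A [protocol_config()].
#' @return Cue frequency in Hz, inside the clamps.
#' @export
treatment_frequency <- function(f0, phase = c("phase1", "phase2"),
                                cfg = protocol_config()) {
  stopifnot(inherits(cfg, "protocol_config"))
  phase <- match.arg(phase)
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("f0 must be a single positive frequency", call. = FALSE)
  ratio <- if (phase == "phase1") cfg$ratio_phase1 else cfg$ratio_phase2
  min(max(ratio * f0, cfg$f_min), cfg$f_max)
}

#' Build the phase plan for one session
#'
#' The session is the baseline interval `[0, baseline_duration)` followed by
#' the treatment time, which is split into two equal halves: phase 1 cued at
#' `ratio_phase1 * f0` and phase 2 at `ratio_phase2 * f0`, both clamped.
#'
#' @param day Protocol day.
#' @param f0 Baseline tremor frequency in Hz.
#' @param significant Whether `f0` came from a significant tremor peak
#'   (`FALSE` when it is the fallback).
#' @param cfg A [protocol_config()].
#' @return A `phase_plan`: list with `day`, `scheduled_duration`,
#'   `baseline_end`, `phase1_end`, `phase1_frequency`, `phase2_frequency`,
#'   `baseline_frequency`, `baseline_significant`.
#' @export
build_phase_plan <- function(day, f0, significant = TRUE,
                             cfg = protocol_config()) {
  total <- scheduled_duration(day, cfg)
  treatment <- total - cfg$baseline_duration
  structure(
    list(day = as.integer(day),
         scheduled_duration = total,
         baseline_end = cfg$baseline_duration,
         phase1_end = cfg$baseline_duration + treatment / 2,
         phase1_frequency = treatment_frequency(f0, "phase1", cfg),
         phase2_frequency = treatment_frequency(f0, "phase2", cfg),
         baseline_frequency = f0,
         baseline_significant = isTRUE(significant)),
    class = "phase_plan"
  )
}

#' @export
print.phase_plan <- function(x, ...) {
  cat(sprintf(paste0("<phase_plan> day %d: baseline 0-%g s, ",
                     "phase 1 @ %.3f Hz to %g s, phase 2 @ %.3f Hz to %g s\n"),
              x$day, x$baseline_end, x$phase1_frequency, x$phase1_end,
              x$phase2_frequency, x$scheduled_duration))
  invisible(x)
}

#' Generate the cue ("tick") times of a session
#'
#' Ticks start at each phase start and repeat at the reciprocal of that
#' phase's cue frequency; no cues sound during the baseline interval. Phase
#' intervals are half-open, so a tick landing exactly on a phase boundary
#' belongs to the next phase.
#'
#' @param plan A `phase_plan` from [build_phase_plan()].
#' @return A `cue_schedule`: list with `tick_times` (seconds from session
#'   start, strictly increasing) and `plan`.
#' @export
generate_cue_times <- function(plan) {
  stopifnot(inherits(plan, "phase_plan"))
  phase_ticks <- function(start, end, freq) {
    if (end <= start) return(numeric(0))
    n <- ceiling((end - start) * freq - 1e-9)
    start + (seq_len(n) - 1L) / freq
  }
  structure(
    list(tick_times = c(
           phase_ticks(plan$baseline_end, plan$phase1_end, plan$phase1_frequency),
           phase_ticks(plan$phase1_end, plan$scheduled_duration, plan$phase2_frequency)),
         plan = plan),
    class = "cue_schedule"
  )
}

#' Session phase and remaining time at a given elapsed time
#'
#' Phases use half-open intervals `[start, end)`; at or beyond the scheduled
#' duration the session is complete. The countdown value is
#' `max(0, scheduled_duration - elapsed)`.
#'
#' @param elapsed Seconds from session start, non-negative; vectorised.
#' @param plan A `phase_plan`.
#' @return List with `phase` (character: `"baseline"`, `"phase1"`,
#'   `"phase2"`, `"complete"`) and `remaining` (seconds), each the length of
#'   `elapsed`.
#' @export
phase_at <- function(elapsed, plan) {
  stopifnot(inherits(plan, "phase_plan"))
  if (any(elapsed < 0)) stop("elapsed must be non-negative", call. = FALSE)
  phase <- ifelse(elapsed < plan$baseline_end, "baseline",
           ifelse(elapsed < plan$phase1_end, "phase1",
           ifelse(elapsed < plan$scheduled_duration, "phase2", "complete")))
  list(phase = phase, remaining = pmax(0, plan$scheduled_duration - elapsed))
}

#' Run a full session offline from a recording
#'
#' Replays the session loop on a recorded (or simulated) accelerometer
#' stream: estimates the baseline tremor frequency from the opening
#' `baseline_duration` seconds, builds the phase plan and cue schedule,
#' tracks the voluntary movement frequency in sliding windows over the
#' treatment portion, scores each window on the biofeedback gauge, and
#' assembles the session log entry. A recording shorter than the schedule is
#' truncated (session ended early), never extrapolated.
#'
#' @param rec An [accel_recording] of at least `cfg$baseline_duration`
#'   seconds.
#' @param day Protocol day.
#' @param cfg A [protocol_config()].
#' @param method Axis-combination rule.
#' @param started_at Session start timestamp, ISO-8601 with timezone offset.
#' @return A `session_result`: list with `plan`, `cues`, `trace`
#'   (a `frequency_trace` in session time), `gauge` (data frame from
#'   [gauge_trace()]), and `log_entry` (a [session_log_entry()]).
#' @export
run_session <- function(rec, day, cfg = protocol_config(),
                        method = c("magnitude", "dominant_axis"),
                        started_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(inherits(rec, "accel_recording"))
  method <- match.arg(method)
  base <- compute_baseline(rec, cfg, method)
  plan <- build_phase_plan(day, base$baseline_frequency, base$significant, cfg)
  cues <- generate_cue_times(plan)
  # completed time is resolved at sample precision: a recording within half a
  # sample period of the schedule counts as complete
  dur <- recording_duration(rec)
  completed <- if (dur >= plan$scheduled_duration - 0.5 / rec$sample_rate)
    plan$scheduled_duration else dur

  fs <- rec$sample_rate
  i_start <- round(plan$baseline_end * fs) + 1L
  i_end <- min(rec$n_samples, round(plan$scheduled_duration * fs))
  series <- combine_axes(rec, method)
  trace <- if (i_end - i_start + 1L >= round(cfg$window_length * fs)) {
    track_frequency(series[i_start:i_end], fs,
                    window_length = cfg$window_length, hop = cfg$hop,
                    band_low = cfg$band_low, band_high = cfg$band_high,
                    min_resolution = cfg$min_resolution,
                    prominence_factor = cfg$prominence_factor,
                    t0 = (i_start - 1L) / fs)
  } else {
    structure(list(window_centers = numeric(0), frequencies = numeric(0),
                   window_length = cfg$window_length, hop = cfg$hop),
              class = "frequency_trace")
  }
  entry <- session_log_entry(
    day = day, started_at = started_at,
    completed_duration = completed,
    scheduled_duration = plan$scheduled_duration,
    baseline_frequency = plan$baseline_frequency,
    baseline_significant = plan$baseline_significant)
  structure(
    list(plan = plan, cues = cues, trace = trace,
         gauge = gauge_trace(trace, plan, cfg), log_entry = entry),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> day %d: baseline %.3f Hz%s, completed %g/%g s\n",
              x$plan$day, x$plan$baseline_frequency,
              if (x$plan$baseline_significant) "" else " (fallback)",
              x$log_entry$completed_duration, x$plan$scheduled_duration))
  invisible(x)
}
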