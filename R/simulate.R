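GRAVITY <- 9.81  # m/s^2

#' Simulation scenario: ground truth for synthetic recordings
#'
#' Bundles every parameter of the tremor / entrained-subject generator so
#' tests and the command line can reproduce a recording exactly from a seed.
#' The tremor model is a sinusoid of known frequency with an optional second
#' harmonic, a slow linear frequency drift, per-axis white Gaussian sensor
#' noise, a gravity offset on one axis, and the oscillation distributed over
#' the three axes by a unit weight vector. The entrained-subject model adds
#' cue-following dynamics: a first-order (exponential) approach, with time
#' constant `tracking_lag`, towards a convex combination of the cue
#' frequency and the native tremor frequency, weighted by `responsiveness`,
#' plus low-pass-filtered Gaussian frequency jitter.
#'
#' @param f_tremor Ground-truth baseline tremor frequency in Hz (default 6,
#'   mid-range for a functional wrist tremor).
#' @param amplitude Oscillation amplitude in m/s^2 (default 1).
#' @param harmonic_ratio Amplitude of the 2x harmonic as a fraction of
#'   `amplitude` (default 0).
#' @param drift_rate Slow linear frequency drift in Hz per minute (default 0).
#' @param noise_sd Per-axis white Gaussian sensor noise, m/s^2 (default 0.1).
#' @param axis_weights Length-3 vector distributing the oscillation across
#'   x, y, z; normalised to unit norm (default mostly-x, some y/z crosstalk).
#' @param gravity_axis Axis carrying the +9.81 m/s^2 gravity offset
#'   (default `"z"`).
#' @param responsiveness How completely the subject adopts the cue frequency,
#'   in `[0, 1]`: 1 = fully entrains, 0 = ignores the cue (default 1).
#' @param tracking_lag Time constant in seconds of the first-order approach
#'   to a new cue frequency (default 1).
#' @param jitter_sd Standard deviation in Hz of the (low-pass-filtered)
#'   frequency jitter of voluntary movement (default 0.05).
#' @param sample_rate Sampling rate in Hz (default 50, covering the tremor
#'   band with margin).
#' @param duration Recording length in seconds (default 60).
#' @param seed Integer RNG seed; identical scenarios give bit-identical
#'   recordings.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(f_tremor = 6, amplitude = 1,
                                harmonic_ratio = 0, drift_rate = 0,
                                noise_sd = 0.1,
                                axis_weights = c(0.80, 0.50, 0.33),
                                gravity_axis = c("z", "x", "y"),
                                responsiveness = 1, tracking_lag = 1,
                                jitter_sd = 0.05,
                                sample_rate = 50, duration = 60, seed = 1L) {
  gravity_axis <- match.arg(gravity_axis)
  if (amplitude < 0 || noise_sd < 0)
    stop("amplitude and noise_sd must be non-negative", call. = FALSE)
  if (f_tremor <= 0) stop("f_tremor must be positive", call. = FALSE)
  if (responsiveness < 0 || responsiveness > 1)
    stop("responsiveness must lie in [0, 1]", call. = FALSE)
  if (tracking_lag <= 0) stop("tracking_lag must be positive", call. = FALSE)
  if (duration <= 0 || sample_rate <= 0)
    stop("duration and sample_rate must be positive", call. = FALSE)
  if (length(axis_weights) != 3L || all(axis_weights == 0))
    stop("axis_weights must be a non-zero length-3 vector", call. = FALSE)
  structure(
    list(f_tremor = f_tremor, amplitude = amplitude,
         harmonic_ratio = harmonic_ratio, drift_rate = drift_rate,
         noise_sd = noise_sd,
         axis_weights = axis_weights / sqrt(sum(axis_weights^2)),
         gravity_axis = gravity_axis,
         responsiveness = responsiveness, tracking_lag = tracking_lag,
         jitter_sd = jitter_sd,
         sample_rate = sample_rate, duration = duration,
         seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Read a simulation scenario from a key-value file
#'
#' Same flat `key = value` format as [read_protocol_config()]; keys must be
#' [simulation_scenario()] argument names (with `axis_weights` as three
#' comma-free space-separated numbers is not supported; use the defaults or
#' construct in R). Unknown keys are rejected.
#'
#' @param path Path to the scenario file.
#' @return A `simulation_scenario`.
#' @export
read_scenario <- function(path) {
  keys <- setdiff(names(formals(simulation_scenario)), "axis_weights")
  do.call(simulation_scenario, read_keyvalue(path, keys))
}

# Run code with a deterministic RNG stream without disturbing the caller's.
with_scenario_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Synthesise the 3-axis recording for a given instantaneous-frequency
# profile f_inst (Hz, one value per sample).
synthesise_recording <- function(sc, f_inst) {
  fs <- sc$sample_rate
  n <- length(f_inst)
  t <- (seq_len(n) - 1L) / fs
  # phase(t) = 2*pi * integral of f; left-Riemann sum on the sample grid
  phase <- 2 * pi * cumsum(c(0, f_inst[-n])) / fs
  s <- sc$amplitude * (sin(phase) + sc$harmonic_ratio * sin(2 * phase))
  axes <- with_scenario_seed(sc$seed, {
    lapply(1:3, function(k)
      sc$axis_weights[k] * s + stats::rnorm(n, sd = sc$noise_sd))
  })
  g_idx <- match(sc$gravity_axis, c("x", "y", "z"))
  axes[[g_idx]] <- axes[[g_idx]] + GRAVITY
  accel_recording(t, axes[[1]], axes[[2]], axes[[3]], sample_rate = fs)
}

#' Simulate a free-running tremor recording
#'
#' The instantaneous tremor frequency is
#' `f(t) = f_tremor + drift_rate * t / 60`; the waveform is
#' `amplitude * (sin(phi(t)) + harmonic_ratio * sin(2 phi(t)))` with
#' `phi` the accumulated phase, distributed over the axes by `axis_weights`,
#' with gravity on `gravity_axis` and i.i.d. Gaussian noise per axis. Fully
#' reproducible from `seed`.
#'
#' @param sc A [simulation_scenario()].
#' @return An [accel_recording].
#' @examples
#' rec <- simulate_tremor(simulation_scenario(f_tremor = 6, duration = 10))
#' estimate_dominant_frequency(combine_axes(rec), rec$sample_rate)
#' @export
simulate_tremor <- function(sc) {
  stopifnot(inherits(sc, "simulation_scenario"))
  n <- round(sc$duration * sc$sample_rate)
  t <- (seq_len(n) - 1L) / sc$sample_rate
  synthesise_recording(sc, sc$f_tremor + sc$drift_rate * t / 60)
}

#' Simulate a subject following the session cues
#'
#' During the baseline interval the subject oscillates at the native tremor
#' frequency. From each phase start the instantaneous voluntary-movement
#' frequency relaxes exponentially (time constant `tracking_lag`) towards
#' the target `responsiveness * cue + (1 - responsiveness) * f_tremor`, with
#' low-pass-filtered Gaussian frequency jitter of standard deviation
#' `jitter_sd` superimposed (0.5 Hz cutoff, so tracker windows remain
#' quasi-stationary). The waveform synthesis is identical to
#' [simulate_tremor()].
#'
#' @param sc A [simulation_scenario()]; `sc$duration` must cover
#'   `plan$scheduled_duration`.
#' @param plan A `phase_plan` from [build_phase_plan()].
#' @return An [accel_recording] of `plan$scheduled_duration` seconds.
#' @export
simulate_entrained_subject <- function(sc, plan) {
  stopifnot(inherits(sc, "simulation_scenario"), inherits(plan, "phase_plan"))
  if (sc$duration < plan$scheduled_duration)
    stop("scenario duration (", sc$duration,
         " s) shorter than the scheduled session (", plan$scheduled_duration,
         " s)", call. = FALSE)
  fs <- sc$sample_rate
  n <- round(plan$scheduled_duration * fs)
  t <- (seq_len(n) - 1L) / fs
  cue <- ifelse(t < plan$baseline_end, NA_real_,
         ifelse(t < plan$phase1_end, plan$phase1_frequency,
                plan$phase2_frequency))
  target <- ifelse(is.na(cue), sc$f_tremor,
                   sc$responsiveness * cue + (1 - sc$responsiveness) * sc$f_tremor)
  # first-order relaxation towards the target, exact per-sample update
  alpha <- 1 - exp(-1 / (fs * sc$tracking_lag))
  f_inst <- numeric(n)
  f_inst[1] <- sc$f_tremor
  for (i in 2:n) f_inst[i] <- f_inst[i - 1] + alpha * (target[i] - f_inst[i - 1])
  if (sc$jitter_sd > 0) {
    jitter <- with_scenario_seed(sc$seed + 1L, stats::rnorm(n))
    beta <- 1 - exp(-2 * pi * 0.5 / fs)  # one-pole low-pass, 0.5 Hz cutoff
    jitter <- stats::filter(beta * jitter, 1 - beta, method = "recursive")
    jitter <- as.numeric(jitter)
    jsd <- stats::sd(jitter)
    if (jsd > 0) jitter <- jitter * sc$jitter_sd / jsd
    f_inst <- pmax(0.1, f_inst + jitter)
  }
  synthesise_recording(sc, f_inst)
}
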