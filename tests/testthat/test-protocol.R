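cfg <- protocol_config()

test_that("scheduled durations follow the seven-day programme", {
  expect_equal(scheduled_duration(1, cfg), 3600)
  expect_equal(scheduled_duration(2, cfg), 1800)
  expect_equal(scheduled_duration(5, cfg), 1800)
  expect_error(scheduled_duration(8, cfg), "1\\.\\.7")
  expect_error(scheduled_duration(0, cfg), "1\\.\\.7")
  # totals over the programme
  total <- sum(vapply(1:7, scheduled_duration, numeric(1), cfg = cfg))
  expect_equal(total, cfg$day1_duration + 6 * cfg$daily_duration)
})

test_that("config invariants and the key-value reader are enforced", {
  expect_error(protocol_config(ratio_phase1 = 1/3, ratio_phase2 = 2/3),
               "ratio_phase2 < ratio_phase1")
  expect_error(protocol_config(f_min = 5, f_max = 2), "f_min < f_max")
  expect_error(protocol_config(baseline_duration = 2000),
               "shorter than every session")
  expect_error(protocol_config(goal_tolerance = 0), "in \\(0, 1\\)")
  expect_error(protocol_config(goal_tolerance = 0.6, half_scale = 0.5),
               "smaller than half_scale")

  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# session lengths", "day1_duration = 300",
               "daily_duration = 200", "f_max = 6"), path)
  got <- read_protocol_config(path)
  expect_equal(got$day1_duration, 300)
  expect_equal(got$f_max, 6)
  expect_equal(got$ratio_phase1, 2 / 3)  # untouched default

  writeLines("frequency_cap = 3", path)
  expect_error(read_protocol_config(path), "unknown key")
  writeLines("day1_duration", path)
  expect_error(read_protocol_config(path), "malformed line")
})

test_that("baseline stage recovers a simulated tremor and matches the
           full-prefix periodogram oracle", {
  rec <- simulate_tremor(simulation_scenario(f_tremor = 5, duration = 12,
                                             noise_sd = 0.2, seed = 3))
  base <- compute_baseline(rec, cfg)
  expect_true(base$significant)
  # one-bin agreement with a single periodogram of the whole 10-s prefix
  prefix <- combine_axes(rec)[seq_len(10 * rec$sample_rate)]
  single <- estimate_dominant_frequency(prefix, rec$sample_rate,
                                        cfg$band_low, cfg$band_high,
                                        cfg$min_resolution,
                                        cfg$prominence_factor)
  expect_lte(abs(base$baseline_frequency - single$dominant_frequency),
             single$resolution)
  expect_lte(abs(base$baseline_frequency - 5), 2 * single$resolution)
})

test_that("baseline stage falls back to f_default without detectable tremor", {
  rec <- simulate_tremor(simulation_scenario(amplitude = 0, noise_sd = 0.3,
                                             duration = 10, seed = 5))
  base <- compute_baseline(rec, cfg)
  expect_false(base$significant)
  expect_equal(base$baseline_frequency, cfg$f_default)

  short <- simulate_tremor(simulation_scenario(duration = 6, seed = 1))
  expect_error(compute_baseline(short, cfg), "shorter than baseline_duration")
})

test_that("treatment frequencies are the phase ratios of baseline, clamped", {
  wide <- protocol_config(f_min = 0.1, f_max = 50)
  expect_equal(treatment_frequency(6, "phase1", wide), 4)
  expect_equal(treatment_frequency(6, "phase2", wide), 2)
  expect_equal(treatment_frequency(2.4, "phase2", cfg), 1)   # 0.8 clamped up
  expect_equal(treatment_frequency(12, "phase1", cfg), 5)    # 8 clamped down
  expect_error(treatment_frequency(0, "phase1", cfg), "positive")
  expect_error(treatment_frequency(-3, "phase2", cfg), "positive")
})

test_that("phase plans split the treatment time into equal halves", {
  p1 <- build_phase_plan(1, 6, TRUE, cfg)
  expect_equal(p1$baseline_end, 10)
  expect_equal(p1$phase1_end, 1805)
  expect_equal(p1$scheduled_duration, 3600)
  p2 <- build_phase_plan(2, 6, TRUE, cfg)
  expect_equal(p2$phase1_end, 905)
  expect_gt(p2$phase1_frequency, p2$phase2_frequency)
})

test_that("phase-plan invariants hold over random configurations", {
  set.seed(99)
  for (i in 1:50) {
    rcfg <- protocol_config(
      baseline_duration = runif(1, 5, 20),
      ratio_phase1 = runif(1, 0.5, 0.9), ratio_phase2 = runif(1, 0.1, 0.45),
      f_min = runif(1, 0.5, 2), f_max = runif(1, 4, 10),
      day1_duration = runif(1, 600, 4000),
      daily_duration = runif(1, 300, 2000))
    day <- sample(1:7, 1)
    f0 <- runif(1, 0.5, 15)
    plan <- build_phase_plan(day, f0, TRUE, rcfg)
    # clamps always hold
    expect_gte(plan$phase1_frequency, rcfg$f_min)
    expect_lte(plan$phase1_frequency, rcfg$f_max)
    expect_gte(plan$phase2_frequency, rcfg$f_min)
    expect_lte(plan$phase2_frequency, rcfg$f_max)
    # equal halves of the treatment time
    expect_equal(plan$phase1_end - plan$baseline_end,
                 plan$scheduled_duration - plan$phase1_end)
    expect_true(0 < plan$baseline_end && plan$baseline_end < plan$phase1_end &&
                plan$phase1_end < plan$scheduled_duration)
    # phases partition [0, scheduled): every probe lands in exactly one phase
    probes <- sort(c(runif(20, 0, plan$scheduled_duration),
                     plan$baseline_end, plan$phase1_end,
                     plan$scheduled_duration))
    ph <- phase_at(probes, plan)
    expect_true(all(ph$phase[probes < plan$scheduled_duration] %in%
                      c("baseline", "phase1", "phase2")))
    expect_true(all(ph$phase[probes >= plan$scheduled_duration] == "complete"))
    expect_equal(ph$remaining, pmax(0, plan$scheduled_duration - probes))
  }
})

test_that("raising the baseline frequency never lowers a cue frequency", {
  f_grid <- seq(0.5, 15, by = 0.25)
  for (phase in c("phase1", "phase2")) {
    fr <- vapply(f_grid, treatment_frequency, numeric(1),
                 phase = phase, cfg = cfg)
    expect_true(all(diff(fr) >= 0))
  }
})

test_that("cue times start at each phase start with reciprocal spacing", {
  wide <- protocol_config(f_min = 0.1, f_max = 50, day1_duration = 30,
                          daily_duration = 20, baseline_duration = 10)
  # one 10-s phase at 2 Hz -> 20 ticks spaced 0.5 s
  plan <- build_phase_plan(2, 6, TRUE, wide)  # phases: [10,15) and [15,20)
  cues <- generate_cue_times(plan)
  in_p1 <- cues$tick_times < plan$phase1_end
  expect_equal(cues$tick_times[1], plan$baseline_end)
  expect_equal(diff(cues$tick_times[in_p1]), rep(1 / plan$phase1_frequency,
                                                 sum(in_p1) - 1),
               tolerance = 1e-9)
  expect_equal(cues$tick_times[which(!in_p1)[1]], plan$phase1_end)

  # day-1 plan at f0 = 6 with wide clamps: 1795 s at 4 Hz -> 7180 ticks +/- 1
  day1 <- build_phase_plan(1, 6, TRUE, protocol_config(f_min = 0.1, f_max = 50))
  ticks <- generate_cue_times(day1)$tick_times
  expect_lte(abs(sum(ticks < day1$phase1_end) - 7180), 1)
  expect_true(all(diff(ticks) > 0))
})

test_that("cue counts equal phase duration times frequency within one", {
  set.seed(7)
  for (i in 1:30) {
    rcfg <- protocol_config(f_min = runif(1, 0.5, 1.5), f_max = runif(1, 4, 9),
                            day1_duration = runif(1, 100, 800),
                            daily_duration = runif(1, 60, 400),
                            baseline_duration = runif(1, 5, 15))
    plan <- build_phase_plan(sample(1:7, 1), runif(1, 1, 12), TRUE, rcfg)
    ticks <- generate_cue_times(plan)$tick_times
    n1 <- sum(ticks >= plan$baseline_end & ticks < plan$phase1_end)
    n2 <- sum(ticks >= plan$phase1_end)
    d1 <- plan$phase1_end - plan$baseline_end
    d2 <- plan$scheduled_duration - plan$phase1_end
    expect_lte(abs(n1 - floor(d1 * plan$phase1_frequency)), 1)
    expect_lte(abs(n2 - floor(d2 * plan$phase2_frequency)), 1)
  }
})

test_that("zero-length phases produce no cues", {
  plan <- build_phase_plan(2, 6, TRUE, cfg)
  plan$phase1_end <- plan$baseline_end  # degenerate phase 1
  ticks <- generate_cue_times(plan)$tick_times
  expect_true(all(ticks >= plan$baseline_end))
  expect_equal(sum(ticks < plan$baseline_end), 0L)
})

test_that("phase_at reports countdown and phase by half-open intervals", {
  plan <- build_phase_plan(1, 6, TRUE, cfg)
  expect_equal(phase_at(5, plan)$phase, "baseline")
  at2000 <- phase_at(2000, plan)
  expect_equal(at2000$phase, "phase2")
  expect_equal(at2000$remaining, 1600)
  done <- phase_at(3600, plan)
  expect_equal(done$phase, "complete")
  expect_equal(done$remaining, 0)
  expect_equal(phase_at(10, plan)$phase, "phase1")  # boundary joins next phase
  expect_error(phase_at(-1, plan), "non-negative")
})

test_that("run_session truncates early-ended recordings, never extrapolates", {
  scfg <- short_config()  # 120-s at-home sessions
  sc <- simulation_scenario(f_tremor = 6, duration = 120, seed = 21)
  plan <- build_phase_plan(2, 6, TRUE, scfg)
  rec <- simulate_entrained_subject(sc, plan)
  full <- run_session(rec, 2, scfg, started_at = "2026-09-19T10:00:00+0000")
  expect_equal(full$log_entry$completed_duration,
               full$log_entry$scheduled_duration)
  expect_false(full$log_entry$ended_early)

  half_idx <- seq_len(rec$n_samples / 2)
  half <- accel_recording(rec$time[half_idx], rec$ax[half_idx],
                          rec$ay[half_idx], rec$az[half_idx], rec$sample_rate)
  part <- run_session(half, 2, scfg, started_at = "2026-09-19T10:00:00+0000")
  expect_equal(part$log_entry$completed_duration /
                 part$log_entry$scheduled_duration, 0.5)
  expect_true(part$log_entry$ended_early)
})

test_that("run_session on a responsive subject recovers the phase-2 goal", {
  scfg <- short_config()
  sc <- simulation_scenario(f_tremor = 6, duration = 120, tracking_lag = 1,
                            responsiveness = 1, jitter_sd = 0.05, seed = 8)
  plan <- build_phase_plan(2, 6, TRUE, scfg)
  rec <- simulate_entrained_subject(sc, plan)
  res <- run_session(rec, 2, scfg)
  g2 <- res$gauge[res$gauge$phase == "phase2", ]
  expect_gt(nrow(g2), 10)
  expect_lte(abs(median(g2$measured, na.rm = TRUE) - res$plan$phase2_frequency),
             0.2)
})
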