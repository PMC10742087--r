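#' Biofeedback gauge needle position
#'
#' Maps a measured voluntary-movement frequency to a needle position on a
#' bounded dial centred on the goal cue frequency. The mapping is linear in
#' the relative frequency error and clipped to `[-1, +1]`:
#' `needle = clip((measured - goal) / (half_scale * goal), -1, +1)`,
#' so the needle is exactly zero when the user matches the goal, deflects
#' fully at a relative error of `half_scale`, and `in_goal` holds whenever
#' the error is within `goal_tolerance * goal`. An undefined measurement (no
#' confident movement peak, `NA`) pegs the needle at -1 so absent movement
#' is visible rather than hidden.
#'
#' @param measured Measured movement frequency in Hz, or `NA` when undefined.
#' @param goal Goal cue frequency in Hz, positive.
#' @param goal_tolerance Goal-range half-width as a fraction of `goal`.
#' @param half_scale Relative error at which the needle saturates; must
#'   exceed `goal_tolerance`.
#' @return A `gauge_reading`: list with `needle` in `[-1, 1]`, `in_goal`,
#'   `measured`, `goal`.
#' @examples
#' gauge_position(4.0, goal = 4.0)$needle   # centred
#' gauge_position(8.0, goal = 4.0)$needle   # saturated high
#' @export
gauge_position <- function(measured, goal, goal_tolerance = 0.10,
                           half_scale = 0.5) {
  if (!is.numeric(goal) || length(goal) != 1L || !is.finite(goal) || goal <= 0)
    stop("goal must be a single positive frequency", call. = FALSE)
  if (!(goal_tolerance > 0 && goal_tolerance < half_scale))
    stop("need 0 < goal_tolerance < half_scale", call. = FALSE)
  if (is.null(measured) || length(measured) != 1L) measured <- NA_real_
  if (is.na(measured)) {
    needle <- -1
    in_goal <- FALSE
  } else {
    needle <- min(1, max(-1, (measured - goal) / (half_scale * goal)))
    in_goal <- abs(measured - goal) <= goal_tolerance * goal
  }
  structure(list(needle = needle, in_goal = in_goal,
                 measured = measured, goal = goal),
            class = "gauge_reading")
}

#' Score a tracked frequency trace on the biofeedback gauge
#'
#' Each tracker window is compared with the goal cue frequency of the phase
#' its centre falls in. Baseline or post-session windows (none are produced
#' by [run_session()], but arbitrary traces are accepted) are scored against
#' the frequency of the nearest treatment phase boundary's phase.
#'
#' @param trace A `frequency_trace` (window centres in session time).
#' @param plan A `phase_plan`.
#' @param cfg A [protocol_config()] supplying `goal_tolerance` and
#'   `half_scale`.
#' @return A data frame with one row per window: `t` (window centre, s),
#'   `phase`, `goal` (Hz), `measured` (Hz or `NA`), `needle`, `in_goal`.
#' @export
gauge_trace <- function(trace, plan, cfg = protocol_config()) {
  stopifnot(inherits(trace, "frequency_trace"), inherits(plan, "phase_plan"),
            inherits(cfg, "protocol_config"))
  n <- length(trace$window_centers)
  if (n == 0L)
    return(data.frame(t = numeric(0), phase = character(0), goal = numeric(0),
                      measured = numeric(0), needle = numeric(0),
                      in_goal = logical(0)))
  phase <- phase_at(trace$window_centers, plan)$phase
  goal <- ifelse(phase %in% c("baseline", "phase1"),
                 plan$phase1_frequency, plan$phase2_frequency)
  readings <- lapply(seq_len(n), function(i)
    gauge_position(trace$frequencies[i], goal[i],
                   cfg$goal_tolerance, cfg$half_scale))
  data.frame(t = trace$window_centers,
             phase = phase,
             goal = goal,
             measured = trace$frequencies,
             needle = vapply(readings, `[[`, numeric(1), "needle"),
             in_goal = vapply(readings, `[[`, logical(1), "in_goal"))
}

#' Export a gauge trace as delimited text
#'
#' @param gauge Data frame from [gauge_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gauge_trace <- function(gauge, path) {
  utils::write.csv(gauge, path, row.names = FALSE)
  invisible(path)
}
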