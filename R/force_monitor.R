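#' One force reading from a window of trajectory steps
#'
#' The ground-truth crush signal: the population mean of the per-agent
#' contact-force magnitude, averaged over the steps of the window (100 steps
#' = one reading per second at dt = 0.01 s). Steps with an empty population
#' contribute 0.
#'
#' @param window Trajectory tibble covering the window (columns `step`,
#'   `contact_force_N`).
#' @param time Time stamp to attach (default: max time seen in the window).
#' @return One-row tibble: `time_s, mean_force_N, max_agent_force_N,
#'   n_agents`.
#' @export
average_force_reading <- function(window, time = NA_real_) {
  steps <- sort(unique(window$step))
  per_step <- vapply(steps, function(s) {
    f <- window$contact_force_N[window$step == s]
    if (length(f) == 0) 0 else mean(f)
  }, numeric(1))
  if (is.na(time)) {
    time <- if ("time_s" %in% names(window)) max(window$time_s) else max(steps)
  }
  tibble::tibble(
    time_s = time,
    mean_force_N = mean(per_step),
    max_agent_force_N = if (nrow(window)) max(window$contact_force_N) else 0,
    n_agents = nrow(window) / max(1L, length(steps)))
}

#' Contact-force series of a trajectory table
#'
#' Slices a trajectory into consecutive windows of `steps_per_reading`
#' recorded steps and emits one [average_force_reading()] per window.
#'
#' @param traj Trajectory tibble (simulator dialect).
#' @param steps_per_reading Window length in steps.
#' @return Tibble of force readings.
#' @export
force_series <- function(traj, steps_per_reading = 100) {
  steps <- sort(unique(traj$step))
  k <- length(steps) %/% steps_per_reading
  out <- vector("list", k)
  for (w in seq_len(k)) {
    sw <- steps[((w - 1) * steps_per_reading + 1):(w * steps_per_reading)]
    win <- traj[traj$step %in% sw, , drop = FALSE]
    out[[w]] <- average_force_reading(win)
  }
  dplyr::bind_rows(out)
}

# Force series from the engine's per-step population statistics.
force_series_from_stats <- function(mean_net, mean_scalar, max_net, n_agents,
                                    times, steps_per_reading = 100) {
  k <- length(mean_net) %/% steps_per_reading
  out <- vector("list", k)
  for (w in seq_len(k)) {
    rows <- ((w - 1) * steps_per_reading + 1):(w * steps_per_reading)
    out[[w]] <- tibble::tibble(
      time_s = times[rows[steps_per_reading]],
      mean_force_N = mean(mean_net[rows]),
      mean_scalar_force_N = mean(mean_scalar[rows]),
      max_agent_force_N = max(max_net[rows]),
      n_agents = mean(n_agents[rows]))
  }
  dplyr::bind_rows(out)
}
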