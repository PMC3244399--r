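agent_cols <- c("x", "y", "vx", "vy", "theta", "radius", "mass", "v0",
                "tau", "id", "spawn_time")

agents_to_matrix <- function(agents) {
  m <- as.matrix(agents[, agent_cols])
  storage.mode(m) <- "double"
  m
}

matrix_to_agents <- function(m, target, exit_ids) {
  colnames(m) <- agent_cols
  d <- tibble::as_tibble(m)
  d$id <- as.integer(d$id)
  d$target_exit <- ifelse(target >= 0, exit_ids[target + 1L], NA_character_)
  d[, c("id", "x", "y", "vx", "vy", "theta", "radius", "mass", "v0", "tau",
        "spawn_time", "target_exit")]
}

# Uniform non-overlapping placement of n agents in a rectangular region,
# keeping clear of the arena's solid walls (doors included: all closed-door
# and wall segments at t = 0).
place_agents <- function(n, region, radius, arena = NULL, max_tries = 500) {
  segs <- NULL
  if (!is.null(arena)) {
    ws <- arena_wall_segments(arena)
    solid <- !(ws$gap_from <= 0 & 0 < ws$gap_until)
    segs <- as.matrix(ws[solid, c("x1", "y1", "x2", "y2")])
  }
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0
  while (placed < n) {
    ok <- FALSE
    r <- radius[placed + 1]
    for (try in seq_len(max_tries)) {
      px <- stats::runif(1, region[1] + r, region[3] - r)
      py <- stats::runif(1, region[2] + r, region[4] - r)
      ok <- TRUE
      if (placed > 0) {
        dd <- sqrt((xs[1:placed] - px)^2 + (ys[1:placed] - py)^2)
        ok <- all(dd >= r + radius[1:placed])
      }
      if (ok && !is.null(segs) && nrow(segs)) {
        for (k in seq_len(nrow(segs))) {
          cp <- closest_point_on_segment(c(px, py), segs[k, 1:2], segs[k, 3:4])
          if (cp$distance < r) { ok <- FALSE; break }
        }
      }
      if (ok) break
    }
    if (!ok) stop("place_agents(): placement region too crowded", call. = FALSE)
    placed <- placed + 1
    xs[placed] <- px; ys[placed] <- py
  }
  cbind(xs, ys)
}

#' Initialise simulation state from a scenario
#'
#' Samples the initial population (positions, body parameters, exit
#' knowledge, targets) using the session RNG. Call `set.seed()` first, or
#' use [simulate_scenario()] which seeds for you.
#'
#' @param spec A `crush_scenario`.
#' @return A list of class `crush_sim_state` with elements `time`,
#'   `step_index`, `agents` (tibble), `known` (list of known-exit vectors,
#'   by agent id), `arena`, `counters`, `credits`.
#' @export
sim_init <- function(spec) {
  n <- spec$initial_agents
  ap <- spec$agent_params
  radius <- stats::runif(n, ap$radius[1], ap$radius[2])
  mass <- stats::runif(n, ap$mass[1], ap$mass[2])
  v0 <- stats::runif(n, ap$v0[1], ap$v0[2])
  pos <- if (n > 0) place_agents(n, spec$placement, radius, spec$arena) else
    matrix(numeric(0), ncol = 2)
  known <- assign_exit_knowledge(n, spec$knowledge, spec$fallback_exit)
  exits <- spec$arena$exits
  target <- character(n)
  theta <- numeric(n)
  for (i in seq_len(n)) {
    target[i] <- nearest_known_open_exit(pos[i, ], known[[i]], exits, 0)
    if (!is.na(target[i])) {
      e <- exits[exits$id == target[i], ]
      theta[i] <- atan2((e$y1 + e$y2) / 2 - pos[i, 2],
                        (e$x1 + e$x2) / 2 - pos[i, 1])
    }
  }
  agents <- tibble::tibble(
    id = seq_len(n), x = pos[, 1], y = pos[, 2], vx = 0, vy = 0,
    theta = theta, radius = radius, mass = mass, v0 = v0, tau = ap$tau,
    spawn_time = 0, target_exit = target)
  names(known) <- as.character(seq_len(n))
  structure(list(time = 0, step_index = 0L, agents = agents, known = known,
                 arena = spec$arena, spec = spec,
                 counters = list(spawned = n, exited = 0L),
                 credits = rep(0, nrow(spec$arena$entrances)),
                 next_id = n + 1L),
            class = "crush_sim_state")
}

target_index <- function(agents, exit_ids) {
  idx <- match(agents$target_exit, exit_ids) - 1L
  idx[is.na(idx)] <- -1L
  idx
}

engine_call <- function(state, fc, dt, n_steps, substeps, disc, record_every,
                        spawn_retries = 20L) {
  a <- state$arena
  segs <- arena_wall_segments(a)
  exits <- as.matrix(a$exits[, c("x1", "y1", "x2", "y2", "open_from", "open_until")])
  entr <- as.matrix(a$entrances[, c("x1", "y1", "x2", "y2", "inflow_rate", "nx", "ny")])
  ap <- state$spec$agent_params
  spawn_pars <- c(ap$mass, ap$radius, ap$v0, ap$tau)
  run_steps_cpp(
    agents_in = agents_to_matrix(state$agents),
    target_in = target_index(state$agents, a$exits$id),
    walls = as.matrix(segs), exits = exits, entrances = entr,
    credits_in = state$credits, spawn_pars = spawn_pars,
    fc = unclass(fc), dt = dt, n_steps = as.integer(n_steps),
    substeps = as.integer(substeps), t0 = state$time,
    step0 = state$step_index, next_id = state$next_id,
    spawned0 = state$counters$spawned, exited0 = state$counters$exited,
    disc = disc, record_every = as.integer(record_every),
    spawn_retries = as.integer(spawn_retries), bounds = a$bounds)
}

default_disc <- function(bounds, n_bins = 8L) {
  list(n_bins = as.integer(n_bins), x_lo = bounds[1], x_hi = bounds[3],
       y_lo = bounds[2], y_hi = bounds[4])
}

#' Advance the simulation by one or more steps
#'
#' Low-level single-chunk stepping of the social-forces dynamics: driving
#' force + psychological repulsion + pairwise contact forces + wall/obstacle
#' forces, semi-implicit Euler with speed clamp, exit absorption and
#' entrance inflow. Mostly useful for tests and small experiments; use
#' [simulate_scenario()] for full runs.
#'
#' @param state A `crush_sim_state` from [sim_init()].
#' @param fc A [force_constants()] object.
#' @param dt Time step, s.
#' @param n_steps Number of steps to advance.
#' @param substeps Physics substeps per step.
#' @return The advanced `crush_sim_state`; the chunk recordings are attached
#'   as attribute `"chunk"`.
#' @export
sim_step <- function(state, fc = force_constants(), dt = 0.01, n_steps = 1,
                     substeps = 1) {
  res <- engine_call(state, fc, dt, n_steps, substeps,
                     default_disc(state$arena$bounds), record_every = 0L)
  new_agents <- matrix_to_agents(res$agents, res$target, state$arena$exits$id)
  state$agents <- new_agents
  state$time <- state$time + n_steps * dt
  state$step_index <- state$step_index + as.integer(n_steps)
  state$counters <- list(spawned = res$spawned, exited = res$exited)
  state$credits <- res$credits
  state$next_id <- res$next_id
  attr(state, "chunk") <- res
  state
}

#' Run a full scenario
#'
#' Advances the scenario for its whole duration, recording one mutual-
#' information reading and one contact-force reading per second (each
#' averaged/pooled over `steps_per_reading` = 100 steps of dt = 0.01 s), the
#' per-exit leaving profile, and trajectory snapshots every `record_every`
#' steps. Door open windows are honoured exactly per step; agents whose
#' target door has closed re-target their nearest known open exit (falling
#' back to the scenario's fallback exit) at the next reading boundary.
#'
#' The detector is entirely passive: it reads positions and headings but
#' never alters them, so trajectories are bit-identical with the detector
#' enabled or disabled.
#'
#' @param spec A `crush_scenario`.
#' @param seed Integer seed; every source of randomness in the run descends
#'   from it.
#' @param fc A [force_constants()] object.
#' @param dt Time step, s (default 0.01; 100 steps = 1 s reading).
#' @param substeps Physics substeps per step (default 1).
#' @param detector A [detector_options()] object, or `FALSE` to skip the MI
#'   computation.
#' @param record_every Trajectory snapshot interval in steps (default 100;
#'   0 disables snapshots).
#' @return A list of class `crush_sim` with tibbles `mi`, `force`,
#'   `leaving`, `trajectory`, plus `counters`, `max_wall_penetration`,
#'   `seed`, and the scenario.
#' @export
simulate_scenario <- function(spec, seed = 1L, fc = force_constants(),
                              dt = 0.01, substeps = 1,
                              detector = detector_options(),
                              record_every = 100L) {
  set.seed(seed)
  opts <- if (isFALSE(detector)) detector_options() else detector
  state <- sim_init(spec)
  disc <- default_disc(spec$arena$bounds, opts$n_bins)
  spr <- opts$steps_per_reading
  n_sec <- ceiling(spec$duration / (spr * dt))
  exits <- spec$arena$exits

  counts_x <- NULL; counts_y <- NULL; counts_th <- NULL
  n_agents <- integer(0); mean_net <- numeric(0); mean_scalar <- numeric(0)
  max_net <- numeric(0); spawned_cum <- integer(0); exited_cum <- integer(0)
  traj <- list(); events <- list()
  max_pen <- 0

  for (sec in seq_len(n_sec)) {
    res <- engine_call(state, fc, dt, spr, substeps, disc, record_every)
    state$agents <- matrix_to_agents(res$agents, res$target, exits$id)
    state$time <- state$time + spr * dt
    state$step_index <- state$step_index + as.integer(spr)
    state$counters <- list(spawned = res$spawned, exited = res$exited)
    state$credits <- res$credits
    state$next_id <- res$next_id

    counts_x <- rbind(counts_x, res$counts_x)
    counts_y <- rbind(counts_y, res$counts_y)
    counts_th <- rbind(counts_th, res$counts_theta)
    n_agents <- c(n_agents, res$n_agents)
    mean_net <- c(mean_net, res$mean_net)
    mean_scalar <- c(mean_scalar, res$mean_scalar)
    max_net <- c(max_net, res$max_net)
    spawned_cum <- c(spawned_cum, res$spawned_cum)
    exited_cum <- c(exited_cum, res$exited_cum)
    if (nrow(res$exit_events)) events[[length(events) + 1]] <- res$exit_events
    if (nrow(res$traj)) traj[[length(traj) + 1]] <- res$traj
    max_pen <- max(max_pen, res$max_wall_penetration)

    # re-target agents whose door has closed (reading-boundary granularity)
    tgt <- state$agents$target_exit
    open_now <- exits$open_from <= state$time & state$time < exits$open_until
    closed <- !is.na(tgt) & !open_now[match(tgt, exits$id)]
    if (any(closed)) {
      for (i in which(closed)) {
        kn <- state$known[[as.character(state$agents$id[i])]]
        if (is.null(kn)) kn <- exits$id  # spawned agents know all exits
        nx <- nearest_known_open_exit(c(state$agents$x[i], state$agents$y[i]),
                                      kn, exits, state$time)
        if (is.na(nx)) nx <- spec$fallback_exit
        # fallback must itself be open; otherwise the agent has no goal
        if (!open_now[match(nx, exits$id)]) nx <- NA_character_
        state$agents$target_exit[i] <- nx
      }
    }
  }

  times <- seq_len(length(n_agents)) * dt
  mi <- NULL
  if (!isFALSE(detector)) {
    mi <- mi_series_from_counts(counts_x, counts_y, counts_th, n_agents,
                                times, opts)
  }
  force <- force_series_from_stats(mean_net, mean_scalar, max_net, n_agents,
                                   times, spr)
  leaving <- if (length(events)) {
    ev <- do.call(rbind, events)
    tibble::tibble(agent_id = as.integer(ev[, 1]), time_s = ev[, 2],
                   exit_id = exits$id[ev[, 3]])
  } else {
    tibble::tibble(agent_id = integer(0), time_s = numeric(0),
                   exit_id = character(0))
  }
  trajectory <- if (length(traj)) {
    tr <- do.call(rbind, traj)
    tibble::tibble(step = as.integer(tr[, 1]), time_s = tr[, 2],
                   agent_id = as.integer(tr[, 3]), x_m = tr[, 4],
                   y_m = tr[, 5], vx = tr[, 6], vy = tr[, 7],
                   theta_rad = tr[, 8], contact_force_N = tr[, 9])
  } else {
    empty_trajectory()
  }
  structure(list(
    mi = mi, force = force, leaving = leaving, trajectory = trajectory,
    per_step = tibble::tibble(step = seq_along(n_agents), time_s = times,
                              n_agents = n_agents, spawned_cum = spawned_cum,
                              exited_cum = exited_cum),
    counters = state$counters, max_wall_penetration = max_pen,
    seed = seed, scenario_label = spec$label, scenario = spec),
    class = "crush_sim")
}

#' @export
print.crush_sim <- function(x, ...) {
  cat(sprintf("<crush_sim> '%s' seed %d: %d spawned, %d exited, %d readings\n",
              x$scenario_label, x$seed, x$counters$spawned, x$counters$exited,
              nrow(x$force)))
  invisible(x)
}

empty_trajectory <- function() {
  tibble::tibble(step = integer(0), time_s = numeric(0), agent_id = integer(0),
                 x_m = numeric(0), y_m = numeric(0), vx = numeric(0),
                 vy = numeric(0), theta_rad = numeric(0),
                 contact_force_N = numeric(0))
}

#' @rdname tidy_crush
#' @export
tidy.crush_sim <- function(x, ...) {
  out <- x$force
  if (!is.null(x$mi)) {
    out <- dplyr::left_join(x$mi, x$force, by = "time_s",
                            suffix = c("", "_force"))
  }
  out
}

#' Tidiers for simulation results
#'
#' `tidy()` on a `crush_sim` returns the per-second MI and force readings as
#' one tibble; `glance()` returns a one-row run summary.
#'
#' @param x A `crush_sim` object.
#' @param ... Unused.
#' @name tidy_crush
#' @return A tibble.
#' @export
glance.crush_sim <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario_label, seed = x$seed,
    spawned = x$counters$spawned, exited = x$counters$exited,
    duration_s = max(x$force$time_s),
    mean_force_N = mean(x$force$mean_force_N),
    mean_mi_bits = if (is.null(x$mi)) NA_real_ else
      mean(x$mi$mi_mean_bits[x$mi$valid], na.rm = TRUE),
    max_wall_penetration_m = x$max_wall_penetration)
}
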