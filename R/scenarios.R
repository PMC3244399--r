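#' Scenario specification
#'
#' Bundles everything a run needs: the arena, duration, the initial
#' population and its placement region, agent parameter distributions, the
#' per-exit knowledge rules, and the fallback exit adopted by agents whose
#' known exits have all closed.
#'
#' @param arena A `crush_arena`.
#' @param duration Run length, s.
#' @param initial_agents Number of agents present at t = 0.
#' @param placement Numeric `c(xmin, ymin, xmax, ymax)` region for initial
#'   placement (uniform, non-overlapping rejection sampling).
#' @param agent_params List with `mass` (length-2 uniform range, kg),
#'   `radius` (range, m), `v0` (range, m/s), `tau` (scalar, s).
#' @param knowledge Named list, one rule per exit id: either
#'   `list(p = <probability>)` or `list(exact_count = <n>)`.
#' @param fallback_exit Exit id granted to agents left with no known exit.
#' @param label Free-text scenario label.
#' @return A list of class `crush_scenario`.
#' @export
scenario_spec <- function(arena, duration, initial_agents, placement,
                          agent_params, knowledge, fallback_exit,
                          label = "scenario") {
  stopifnot(duration > 0, initial_agents >= 0)
  stopifnot(all(names(knowledge) %in% arena$exits$id))
  for (rule in knowledge) {
    stopifnot(xor(!is.null(rule$p), !is.null(rule$exact_count)))
    if (!is.null(rule$p)) stopifnot(rule$p >= 0, rule$p <= 1)
    if (!is.null(rule$exact_count)) {
      stopifnot(rule$exact_count >= 0, rule$exact_count <= initial_agents)
    }
  }
  stopifnot(fallback_exit %in% arena$exits$id)
  structure(list(arena = arena, duration = duration,
                 initial_agents = as.integer(initial_agents),
                 placement = as.numeric(placement),
                 agent_params = agent_params, knowledge = knowledge,
                 fallback_exit = fallback_exit, label = label),
            class = "crush_scenario")
}

#' @export
print.crush_scenario <- function(x, ...) {
  cat(sprintf("<crush_scenario> '%s': %d initial agents, %.0f s\n",
              x$label, x$initial_agents, x$duration))
  print(x$arena)
  invisible(x)
}

#' Benchmark room scenario
#'
#' A single rectangular room (default 20 m x 10 m) with a wide exit on the
#' east wall, an identical entrance on the west wall, and a central
#' rectangular obstacle that disrupts the flow. Two modes:
#' `normal` starts with 20 agents at the west and injects 10 agents/s at the
#' default desired speed; `evacuation` overwhelms the structure with
#' 30 agents/s at an elevated desired escape speed.
#'
#' @param mode `"normal"` or `"evacuation"`.
#' @param room Room size `c(width, height)`, m.
#' @param door_width Exit/entrance width, m.
#' @param obstacle_size Central obstacle `c(width, height)`, m.
#' @param duration Run length, s (default 120).
#' @param inflow_rate Agents per second (default 10 normal / 30 evacuation).
#' @param v0 Desired-speed range, m/s (default centred on 1.25 normal /
#'   2.0 evacuation).
#' @return A `crush_scenario`.
#' @export
build_benchmark <- function(mode = c("normal", "evacuation"),
                            room = c(20, 10), door_width = 8,
                            obstacle_size = c(2, 4), duration = 120,
                            inflow_rate = NULL, v0 = NULL) {
  mode <- match.arg(mode)
  if (is.null(inflow_rate)) inflow_rate <- if (mode == "normal") 10 else 30
  if (is.null(v0)) {
    v0 <- if (mode == "normal") c(1.0, 1.5) else c(1.75, 2.25)
  }
  W <- room[1]; H <- room[2]
  dy <- c((H - door_width) / 2, (H + door_width) / 2)
  ob <- obstacle(rbind(
    c((W - obstacle_size[1]) / 2, (H - obstacle_size[2]) / 2),
    c((W + obstacle_size[1]) / 2, (H - obstacle_size[2]) / 2),
    c((W + obstacle_size[1]) / 2, (H + obstacle_size[2]) / 2),
    c((W - obstacle_size[1]) / 2, (H + obstacle_size[2]) / 2)))
  a <- arena(
    bounds = c(0, 0, W, H),
    obstacles = list(ob),
    exits = exit_door("east", W, dy[1], W, dy[2]),
    entrances = entrance("west", 0, dy[1], 0, dy[2], inflow_rate, 1, 0))
  scenario_spec(
    arena = a, duration = duration, initial_agents = 20,
    placement = c(0.3, dy[1], 3.0, dy[2]),
    agent_params = list(mass = c(60, 90), radius = c(0.25, 0.30),
                        v0 = v0, tau = 0.5),
    knowledge = list(east = list(p = 1.0)),
    fallback_exit = "east",
    label = paste0("benchmark-", mode))
}

#' Generic multi-exit club scenario
#'
#' A four-exit, club-like arena with interior partition walls (the geometry
#' is generic, not any specific venue). The defaults carry the mechanics of
#' a representative nightclub evacuation: 450 patrons; everyone knows the
#' main door, half know the bar door, a quarter know the stage door, and
#' exactly 12 know the kitchen door; the stage door becomes impassable 30 s
#' into the run; the main door is the fallback.
#'
#' @param population Initial population (default 450).
#' @param duration Run length, s (default 300).
#' @param stage_closes_at Stage-door closure time, s (default 30; `Inf` for
#'   the idealised variant).
#' @param knowledge Per-exit knowledge rules (see [scenario_spec()]);
#'   `NULL` for the defaults above. Use `p = 1` on all exits for the
#'   idealised variant.
#' @return A `crush_scenario`.
#' @export
build_club <- function(population = 450, duration = 300, stage_closes_at = 30,
                       knowledge = NULL) {
  stopifnot(population >= 1)
  if (is.null(knowledge)) {
    knowledge <- list(main = list(p = 1.0), bar = list(p = 0.5),
                      stage = list(p = 0.25), kitchen = list(exact_count = 12))
  }
  W <- 24; H <- 18
  exits <- dplyr::bind_rows(
    exit_door("main", 10, 0, 13, 0),                       # south, wide
    exit_door("bar", 24, 6, 24, 8),                        # east
    exit_door("stage", 0, 12, 0, 14, open_until = stage_closes_at),  # west
    exit_door("kitchen", 20, 18, 22, 18))                  # north
  # Interior partitions: stubs with wide doorways so straight-line routes
  # stay feasible (no path planning is modelled).
  walls <- dplyr::bind_rows(
    wall(0, 10, 6, 10),    # stage-room partition, gap to the east
    wall(16, 18, 16, 14),  # kitchen corner partition, gap to the south
    wall(18, 6, 24, 6))    # bar partition, gap to the west
  a <- arena(bounds = c(0, 0, W, H), walls = walls, exits = exits,
             entrances = NULL)
  kn <- knowledge
  if (!is.null(kn$kitchen$exact_count) && kn$kitchen$exact_count > population) {
    stop("build_club(): exact_count exceeds population", call. = FALSE)
  }
  scenario_spec(
    arena = a, duration = duration, initial_agents = population,
    placement = c(1, 1, 23, 16),
    agent_params = list(mass = c(60, 90), radius = c(0.25, 0.30),
                        v0 = c(1.0, 1.5), tau = 0.5),
    knowledge = kn, fallback_exit = "main", label = "club")
}

#' Assign exit knowledge to a population
#'
#' Probability rules draw independent Bernoulli(p) knowledge per agent per
#' exit; `exact_count` rules grant knowledge to a uniformly random subset of
#' exactly that many agents (the count is met for every seed; membership
#' varies). Agents ending with an empty set are granted the fallback exit.
#'
#' @param n_agents Population size.
#' @param knowledge Named list of per-exit rules (see [scenario_spec()]).
#' @param fallback_exit Exit id injected for empty knowledge sets.
#' @return List of length `n_agents`; each element a character vector of
#'   known exit ids.
#' @export
assign_exit_knowledge <- function(n_agents, knowledge, fallback_exit) {
  known <- replicate(n_agents, character(0), simplify = FALSE)
  for (ex in names(knowledge)) {
    rule <- knowledge[[ex]]
    if (!is.null(rule$p)) {
      hit <- stats::runif(n_agents) < rule$p
    } else {
      stopifnot(rule$exact_count <= n_agents)
      hit <- logical(n_agents)
      hit[sample.int(n_agents, rule$exact_count)] <- TRUE
    }
    for (i in which(hit)) known[[i]] <- c(known[[i]], ex)
  }
  empty <- lengths(known) == 0
  for (i in which(empty)) known[[i]] <- fallback_exit
  attr(known, "fallback_granted") <- sum(empty)
  known
}

#' Serialize a scenario to JSON
#'
#' @param spec A `crush_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path) {
  a <- spec$arena
  exits <- as.data.frame(a$exits)
  # JSON has no Inf: an absent / null open_until means "never closes"
  exits$open_until[!is.finite(exits$open_until)] <- NA_real_
  doc <- list(
    schema = "crushmi-scenario-1",
    label = spec$label,
    duration = spec$duration,
    initial_agents = spec$initial_agents,
    placement = spec$placement,
    agent_params = spec$agent_params,
    knowledge = spec$knowledge,
    fallback_exit = spec$fallback_exit,
    arena = list(
      bounds = a$bounds,
      walls = as.data.frame(a$walls),
      obstacles = lapply(a$obstacles, function(m) unclass(as.matrix(m))),
      exits = exits,
      entrances = as.data.frame(a$entrances)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scenario from JSON
#'
#' @param path File written by [write_scenario()].
#' @return A `crush_scenario`.
#' @export
read_scenario <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(doc$schema, "crushmi-scenario-1"))
  ex <- tibble::as_tibble(doc$arena$exits)
  if (is.null(ex[["open_until"]])) ex$open_until <- NA_real_
  ex$open_until[is.na(ex$open_until)] <- Inf  # JSON has no Inf
  walls <- tibble::as_tibble(doc$arena$walls)
  entr <- tibble::as_tibble(doc$arena$entrances)
  obs_raw <- doc$arena$obstacles  # simplifyVector folds equal-size polygons
  obstacles <- if (is.array(obs_raw) && length(dim(obs_raw)) == 3) {
    lapply(seq_len(dim(obs_raw)[1]), function(i) obstacle(obs_raw[i, , ]))
  } else {
    lapply(obs_raw, obstacle)
  }
  kn <- lapply(doc$knowledge, function(r) r[!vapply(r, is.null, TRUE)])
  a <- arena(bounds = doc$arena$bounds,
             walls = if (nrow(walls)) walls else NULL,
             obstacles = obstacles, exits = ex,
             entrances = if (nrow(entr)) entr else NULL)
  scenario_spec(arena = a, duration = doc$duration,
                initial_agents = doc$initial_agents,
                placement = doc$placement,
                agent_params = doc$agent_params,
                knowledge = kn, fallback_exit = doc$fallback_exit,
                label = doc$label)
}
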