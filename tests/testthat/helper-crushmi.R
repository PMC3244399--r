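# Independent brute-force MI oracle: the literal double sum
# sum_ab p(a,b) log2( p(a,b) / (p(a) p(b)) ), cell by cell.
mi_double_sum <- function(counts) {
  counts <- as.matrix(counts)
  N <- sum(counts)
  p <- counts / N
  pr <- rowSums(p)
  pc <- colSums(p)
  mi <- 0
  for (a in seq_len(nrow(p))) {
    for (b in seq_len(ncol(p))) {
      if (p[a, b] > 0) {
        mi <- mi + p[a, b] * log2(p[a, b] / (pr[a] * pc[b]))
      }
    }
  }
  mi
}

random_count_table <- function(max_dim = 8, max_count = 30) {
  B1 <- sample(2:max_dim, 1)
  B2 <- sample(2:max_dim, 1)
  m <- matrix(rpois(B1 * B2, lambda = runif(1, 0.5, 5)), B1, B2)
  if (sum(m) == 0) m[1, 1] <- 1
  m
}

# A bare single-exit room with no obstacle, for engine unit tests.
test_room <- function(width = 10, height = 6, door = 2, inflow = 0) {
  dy <- c((height - door) / 2, (height + door) / 2)
  arena(bounds = c(0, 0, width, height),
        exits = exit_door("east", width, dy[1], width, dy[2]),
        entrances = if (inflow > 0)
          entrance("west", 0, dy[1], 0, dy[2], inflow, 1, 0) else NULL)
}

# Minimal scenario wrapper around test_room() with n initial agents placed
# in a box at the west end.
test_scenario <- function(n = 0, inflow = 0, duration = 10, width = 10,
                          height = 6, door = 2, v0 = c(1.0, 1.5)) {
  scenario_spec(
    arena = test_room(width, height, door = door, inflow = inflow),
    duration = duration, initial_agents = n,
    placement = c(0.5, 0.5, width / 2, height - 0.5),
    agent_params = list(mass = c(60, 90), radius = c(0.25, 0.30),
                        v0 = v0, tau = 0.5),
    knowledge = list(east = list(p = 1.0)),
    fallback_exit = "east", label = "test-room")
}

# Hand-built sim state (bypasses random placement) for force-level tests.
manual_state <- function(agents, spec) {
  known <- replicate(nrow(agents), spec$arena$exits$id, simplify = FALSE)
  names(known) <- as.character(agents$id)
  structure(list(time = 0, step_index = 0L, agents = agents, known = known,
                 arena = spec$arena, spec = spec,
                 counters = list(spawned = nrow(agents), exited = 0L),
                 credits = rep(0, nrow(spec$arena$entrances)),
                 next_id = max(c(0L, agents$id)) + 1L),
            class = "crush_sim_state")
}
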