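fc <- force_constants()

test_that("a lone agent at desired speed translates towards its goal", {
  spec <- test_scenario()
  ag <- agent(1, x = 3, y = 3, vx = 1.2, vy = 0, v0 = 1.2,
              target_exit = "east")
  st <- manual_state(ag, spec)
  st2 <- sim_step(st, fc, dt = 0.01, n_steps = 10)
  # goal is dead east: velocity is at the fixed point, pure translation
  expect_equal(st2$agents$x, 3 + 1.2 * 0.1, tolerance = 1e-9)
  expect_equal(st2$agents$y, 3, tolerance = 1e-9)
  expect_equal(st2$agents$theta, 0, tolerance = 1e-9)
})

test_that("two overlapping static agents separate", {
  spec <- test_scenario()
  crowd <- dplyr::bind_rows(
    agent(1, 4.0, 3, v0 = 0, radius = 0.28),
    agent(2, 4.4, 3, v0 = 0, radius = 0.28))
  st <- manual_state(crowd, spec)
  d0 <- abs(diff(st$agents$x))
  st2 <- sim_step(st, fc, dt = 0.01, n_steps = 1)
  d1 <- sqrt(diff(st2$agents$x)^2 + diff(st2$agents$y)^2)
  expect_gt(d1, d0)
})

test_that("an empty population advances time only", {
  spec <- test_scenario()
  st <- manual_state(agent(1, 1, 1)[0, ], spec)
  st2 <- sim_step(st, fc, dt = 0.01, n_steps = 5)
  expect_equal(st2$time, 0.05)
  expect_equal(nrow(st2$agents), 0)
  expect_equal(st2$counters, list(spawned = 0L, exited = 0L))
})

test_that("spawn accumulator: rate times time, deterministically", {
  # rate 10/s over 5 s -> exactly 50; rate 30/s over 1 s -> exactly 30
  for (case in list(c(10, 5, 50), c(30, 1, 30), c(0, 5, 0))) {
    spec <- test_scenario(n = 0, inflow = case[1], duration = case[2],
                          width = 30, height = 10, door = 8)
    sim <- simulate_scenario(spec, seed = 5, record_every = 0)
    expect_equal(sim$counters$spawned, case[3])
  }
})

test_that("agents are absorbed at open exits but not closed ones", {
  a <- arena(bounds = c(0, 0, 10, 6),
             exits = dplyr::bind_rows(
               exit_door("east", 10, 2, 10, 4),
               exit_door("north", 4, 6, 6, 6, open_from = 100)))
  spec <- scenario_spec(a, duration = 10, initial_agents = 0,
                        placement = c(1, 1, 2, 2),
                        agent_params = list(mass = c(70, 70),
                                            radius = c(0.27, 0.27),
                                            v0 = c(1, 1), tau = 0.5),
                        knowledge = list(east = list(p = 1)),
                        fallback_exit = "east")
  # agent touching the open east exit is removed
  st <- manual_state(agent(1, 9.8, 3, radius = 0.27, target_exit = "east"), spec)
  st2 <- sim_step(st, fc, n_steps = 1)
  expect_equal(nrow(st2$agents), 0)
  expect_equal(st2$counters$exited, 1L)
  expect_equal(st2$counters$spawned, 1L)  # conservation: 1 = 0 inside + 1 out

  # agent touching the closed north exit is not removed (and the closed door
  # acts as a wall, so it is pushed back rather than leaking out)
  st3 <- manual_state(agent(2, 5, 5.8, radius = 0.27, target_exit = "north"),
                      spec)
  st4 <- sim_step(st3, fc, n_steps = 1)
  expect_equal(nrow(st4$agents), 1)
  expect_equal(st4$counters$exited, 0L)
})

test_that("count conservation holds at every step of a benchmark run", {
  sim <- simulate_scenario(build_benchmark("normal", duration = 15), seed = 3)
  with(sim$per_step,
       expect_true(all(n_agents == spawned_cum - exited_cum)))
  expect_equal(sim$counters$spawned,
               nrow(sim$leaving) + tail(sim$per_step$n_agents, 1))
})

test_that("identical seed and scenario give a bit-identical run", {
  spec <- build_benchmark("normal", duration = 8)
  s1 <- simulate_scenario(spec, seed = 11)
  s2 <- simulate_scenario(spec, seed = 11)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$mi, s2$mi)
  expect_identical(s1$force, s2$force)
  s3 <- simulate_scenario(spec, seed = 12)
  expect_false(identical(s1$trajectory, s3$trajectory))
})

test_that("the MI detector is passive: disabling it leaves trajectories intact", {
  spec <- build_benchmark("normal", duration = 6)
  on <- simulate_scenario(spec, seed = 4, detector = detector_options())
  off <- simulate_scenario(spec, seed = 4, detector = FALSE)
  expect_identical(on$trajectory, off$trajectory)
  expect_null(off$mi)
})

test_that("engine contact forces match the direct R computation", {
  set.seed(55)
  spec <- test_scenario()
  crowd <- dplyr::bind_rows(lapply(1:25, function(i)
    agent(i, runif(1, 0.6, 6), runif(1, 0.6, 5.4), vx = runif(1, -1, 1),
          vy = runif(1, -1, 1), radius = runif(1, 0.25, 0.3),
          v0 = 0)))
  st <- manual_state(crowd, spec)
  st2 <- sim_step(st, fc, dt = 1e-9, n_steps = 1)
  chunk <- attr(st2, "chunk")
  ref <- contact_magnitudes(crowd, spec$arena, fc, time = 0)
  expect_equal(chunk$mean_net[1], mean(ref$net_N), tolerance = 1e-6)
  expect_equal(chunk$mean_scalar[1], mean(ref$scalar_N), tolerance = 1e-6)
  expect_equal(chunk$max_net[1], max(ref$net_N), tolerance = 1e-6)
})

test_that("no wall penetration beyond 0.05 m on the benchmark scenario", {
  sim <- simulate_scenario(build_benchmark("normal", duration = 30), seed = 21)
  expect_lt(sim$max_wall_penetration, 0.05)
})

test_that("agents re-target when their door closes", {
  a <- arena(bounds = c(0, 0, 10, 6),
             exits = dplyr::bind_rows(
               exit_door("near", 10, 2, 10, 4, open_until = 2),
               exit_door("far", 0, 2, 0, 4)))
  spec <- scenario_spec(a, duration = 20, initial_agents = 3,
                        placement = c(6.5, 2, 8, 4),
                        agent_params = list(mass = c(70, 70),
                                            radius = c(0.27, 0.27),
                                            v0 = c(1, 1), tau = 0.5),
                        knowledge = list(near = list(p = 1), far = list(p = 1)),
                        fallback_exit = "far")
  # agents start nearer the 'near' door but cannot reach it before it closes
  # at t = 2 s, so every one of them must leave through 'far'
  sim <- simulate_scenario(spec, seed = 2)
  expect_equal(sim$counters$exited, 3L)
  expect_true(all(sim$leaving$exit_id == "far"))
  expect_true(all(sim$leaving$time_s > 2))
  # the retarget rule itself
  expect_equal(nearest_known_open_exit(c(8, 3), c("near", "far"),
                                       a$exits, time = 3), "far")
  expect_equal(nearest_known_open_exit(c(8, 3), c("near", "far"),
                                       a$exits, time = 1), "near")
})
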