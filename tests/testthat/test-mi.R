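test_that("discretize: edges, clamping, arithmetic, periodic wrap", {
  sp <- discretizer_spec(8, 0, 8)
  expect_equal(discretize(0, sp), 0)        # lower edge
  expect_equal(discretize(8, sp), 7)        # upper edge, right-closed last bin
  expect_equal(discretize(3.5, sp), 3)      # floor((v - lo) / w)
  expect_equal(discretize(c(-2, 100), sp), c(0, 7))  # clamped
  expect_error(discretize(NaN, sp), "non-finite")

  th <- discretizer_spec(8, -pi, pi, periodic = TRUE)
  # -pi and pi are the same angle: both must land in the top bin
  expect_equal(discretize(pi, th), 7)
  expect_equal(discretize(-pi, th), 7)
  expect_equal(discretize(3 * pi, th), discretize(pi, th))
})

test_that("mi_from_counts: known tables", {
  expect_equal(mi_from_counts(rbind(c(5, 0), c(0, 5))), 1.0)   # deterministic
  expect_equal(mi_from_counts(rbind(c(25, 25), c(25, 25))), 0) # independent
  expect_equal(mi_from_counts(rbind(c(4, 2), c(2, 4))),
               mi_double_sum(rbind(c(4, 2), c(2, 4))), tolerance = 1e-14)
  expect_equal(mi_from_counts(rbind(c(4, 2), c(2, 4))), 0.0817, tolerance = 1e-3)
  expect_error(mi_from_counts(matrix(0, 2, 2)), "empty")
})

test_that("mi_from_counts agrees with the brute-force double sum", {
  set.seed(41)
  for (k in 1:1000) {
    m <- random_count_table()
    expect_equal(mi_from_counts(m), mi_double_sum(m), tolerance = 1e-12)
  }
})

test_that("MI is bounded by marginal entropies and log2(B)", {
  set.seed(42)
  ent <- function(q) { q <- q[q > 0] / sum(q); -sum(q * log2(q)) }
  for (k in 1:200) {
    m <- random_count_table()
    mi <- mi_from_counts(m)
    expect_gte(mi, 0)
    expect_lte(mi, min(ent(rowSums(m)), ent(colSums(m))) + 1e-12)
    expect_lte(mi, log2(max(dim(m))))
  }
})

test_that("pooled pairwise MI matches exhaustive pair enumeration", {
  # 4 agents, 2 in bin 0 and 2 in bin 1, one step: enumerate the 12 ordered
  # pairs by hand -> joint [[2,4],[4,2]]
  traj <- tibble::tibble(step = 1L, agent_id = 1:4,
                         x_m = c(0.5, 0.5, 1.5, 1.5),
                         y_m = 0, theta_rad = 0, time_s = 0.01)
  sp <- discretizer_spec(2, 0, 2)
  got <- pairwise_population_mi(traj, "x", sp)
  expect_equal(got, mi_double_sum(rbind(c(2, 4), c(4, 2))), tolerance = 1e-12)

  # identical constant values: zero marginal entropy, zero MI
  traj2 <- tibble::tibble(step = rep(1:3, each = 4), agent_id = rep(1:4, 3),
                          x_m = 1, y_m = 0, theta_rad = 0)
  expect_equal(pairwise_population_mi(traj2, "x", sp), 0)

  # fewer than 2 agents at every step: undefined
  traj3 <- tibble::tibble(step = 1:5, agent_id = 1L, x_m = runif(5),
                          y_m = 0, theta_rad = 0)
  expect_error(pairwise_population_mi(traj3, "x", sp), "fewer than 2")
})

test_that("independent uniform draws stay below the null quantile", {
  set.seed(43)
  B <- 8
  sp <- discretizer_spec(B, 0, 1)
  n_agents <- 60; n_steps <- 50
  traj <- tibble::tibble(
    step = rep(seq_len(n_steps), each = n_agents),
    agent_id = rep(seq_len(n_agents), n_steps),
    x_m = runif(n_agents * n_steps), y_m = 0, theta_rad = 0)
  mi <- pairwise_population_mi(traj, "x", sp, policy = pair_policy(2e6))
  N <- n_steps * n_agents * (n_agents - 1)
  expect_lt(mi, mi_null_quantile(B, N))
  # and the null quantile is of the same order as the bias bound
  expect_lt(mi_null_quantile(B, N) / mi_bias_bound(B, N), 3)
})

test_that("pair budget subsampling preserves the MI level", {
  set.seed(44)
  n_agents <- 40; n_steps <- 60
  # strongly dependent fixture: platoon drifting across bins
  traj <- fixture_trajectory("laminar", n_agents, n_steps, seed = 44)
  sp <- discretizer_spec(8, 0, 20)
  full <- pairwise_population_mi(traj, "x", sp, policy = pair_policy(1e8))
  sub <- pairwise_population_mi(traj, "x", sp, policy = pair_policy(2e4))
  expect_gt(full, 0.3)
  expect_equal(sub, full, tolerance = 0.15)
})

test_that("a frozen configuration carries little MI, shrinking with n", {
  # a static crowd is a single configuration: its all-pairs MI is a pure
  # finite-population artefact of order 1/n, identical in both modes
  static_mi <- function(n, mode) {
    traj <- tibble::tibble(step = rep(1:20, each = n),
                           agent_id = rep(seq_len(n), 20),
                           x_m = rep(seq(0.5, 9.5, length.out = n), 20),
                           y_m = 0, theta_rad = 0)
    pairwise_population_mi(traj, "x", discretizer_spec(8, 0, 10), mode = mode)
  }
  expect_lt(static_mi(40, "pooled"), 0.05)
  expect_lt(static_mi(40, "average_per_step"), 0.05)
  expect_lt(static_mi(80, "pooled"), static_mi(10, "pooled"))
  # both modes agree exactly on a time-constant window
  expect_equal(static_mi(20, "pooled"), static_mi(20, "average_per_step"),
               tolerance = 1e-12)
})

test_that("mi_reading flags windows with too few agents invalid", {
  traj <- tibble::tibble(step = rep(1:100, each = 2), agent_id = rep(1:2, 100),
                         x_m = runif(200, 0, 20), y_m = runif(200, 0, 10),
                         theta_rad = runif(200, -pi, pi), time_s = 1)
  specs <- list(x = discretizer_spec(8, 0, 20), y = discretizer_spec(8, 0, 10),
                theta = discretizer_spec(8, -pi, pi, periodic = TRUE))
  r <- mi_reading(traj, specs, n_min = 10)
  expect_false(r$valid)
  expect_true(is.na(r$mi_mean_bits))
  r2 <- mi_reading(traj, specs, n_min = 2)
  expect_true(r2$valid)
  expect_false(is.na(r2$mi_mean_bits))
})

test_that("mi_series slices a trajectory into per-window readings", {
  traj <- fixture_trajectory("laminar", n_agents = 20, n_steps = 250, seed = 7)
  s <- mi_series(traj, bounds = c(0, 0, 20, 10),
                 detector_options(steps_per_reading = 100, n_min = 5))
  expect_equal(nrow(s), 2)  # 250 steps -> 2 full windows
  expect_true(all(s$valid))
  expect_equal(s$mi_theta_bits, c(0, 0))
})
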