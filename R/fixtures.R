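#' Synthetic trajectory fixtures with known order structure
#'
#' Generates trajectory tables in the simulator's own dialect so the MI
#' detector can be exercised (and calibrated) without running the simulator:
#'
#' * `laminar` — a compact platoon of agents in parallel lanes translating
#'   east at a common speed. All headings are identical (so heading MI is
#'   exactly zero: zero marginal entropy), while the platoon's x-bin
#'   occupancy moves coherently through the window, making the x-bins of
#'   paired agents deterministically related.
#' * `turbulent` — positions and headings independently resampled uniformly
#'   for every agent at every step: the fully disordered null.
#' * `gaussian` — two agents whose x-values are drawn from a bivariate
#'   normal with correlation `rho` each step (y independent standard
#'   normal, heading uniform), for closed-form MI checks against
#'   `-0.5 * log2(1 - rho^2)`.
#'
#' @param kind `"laminar"`, `"turbulent"` or `"gaussian"`.
#' @param n_agents Number of agents (>= 2; `gaussian` uses exactly 2).
#' @param n_steps Number of steps.
#' @param rho Correlation for `gaussian`, in (-1, 1).
#' @param seed Integer seed, or `NULL` to use the session RNG.
#' @param bounds Arena bounds for `laminar`/`turbulent`
#'   (default `c(0, 0, 20, 10)`).
#' @param dt Step length, s.
#' @return A trajectory tibble (`step, time_s, agent_id, x_m, y_m, vx, vy,
#'   theta_rad, contact_force_N`).
#' @export
fixture_trajectory <- function(kind = c("laminar", "turbulent", "gaussian"),
                               n_agents = 50, n_steps = 100, rho = 0.9,
                               seed = NULL, bounds = c(0, 0, 20, 10),
                               dt = 0.01) {
  kind <- match.arg(kind)
  stopifnot(n_agents >= 2, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "gaussian") {
    stopifnot(rho > -1, rho < 1)
    n_agents <- 2L
    z1 <- stats::rnorm(n_steps)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_steps)
    df <- tibble::tibble(
      step = rep(seq_len(n_steps), each = 2L),
      agent_id = rep(1:2, n_steps),
      x_m = as.vector(rbind(z1, z2)),
      y_m = stats::rnorm(2L * n_steps),
      theta_rad = stats::runif(2L * n_steps, -pi, pi))
  } else if (kind == "turbulent") {
    n <- n_agents * n_steps
    df <- tibble::tibble(
      step = rep(seq_len(n_steps), each = n_agents),
      agent_id = rep(seq_len(n_agents), n_steps),
      x_m = stats::runif(n, bounds[1], bounds[3]),
      y_m = stats::runif(n, bounds[2], bounds[4]),
      theta_rad = stats::runif(n, -pi, pi))
  } else {
    # platoon narrower than one x-bin (at the default 8 bins), crossing two
    # bins per 100 steps; lanes spread in y
    binw <- (bounds[3] - bounds[1]) / 8
    speed <- 2 * binw / (100 * dt)
    x0 <- bounds[1] + 1.0 +
      (seq_len(n_agents) - 1) %% 5 * (0.3 * binw / 5)
    lane <- bounds[2] + (seq_len(n_agents) - 0.5) *
      (bounds[4] - bounds[2]) / n_agents
    span <- bounds[3] - bounds[1] - 2
    steps <- rep(seq_len(n_steps), each = n_agents)
    ids <- rep(seq_len(n_agents), n_steps)
    x <- bounds[1] + 1 + (x0[ids] - bounds[1] - 1 + speed * (steps - 1) * dt) %% span
    df <- tibble::tibble(step = steps, agent_id = ids, x_m = x,
                         y_m = lane[ids], theta_rad = 0)
  }
  df$time_s <- df$step * dt
  df$vx <- if (kind == "laminar") 2 * (bounds[3] - bounds[1]) / 8 else cos(df$theta_rad)
  df$vy <- if (kind == "laminar") 0 else sin(df$theta_rad)
  df$contact_force_N <- 0
  df[, c("step", "time_s", "agent_id", "x_m", "y_m", "vx", "vy",
         "theta_rad", "contact_force_N")]
}

#' Shuffle one margin of a trajectory's pair structure
#'
#' Destroys inter-agent (and cross-time) dependence in one variable by
#' permuting its values across all rows of the table, for permutation-null
#' checks of the MI estimator.
#'
#' @param traj Trajectory tibble.
#' @param variable `"x"`, `"y"` or `"theta"`.
#' @return The permuted trajectory tibble.
#' @export
shuffle_margin <- function(traj, variable = c("x", "y", "theta")) {
  variable <- match.arg(variable)
  col <- switch(variable, x = "x_m", y = "y_m", theta = "theta_rad")
  traj[[col]] <- sample(traj[[col]])
  traj
}
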