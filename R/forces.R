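#' Social-force model constants
#'
#' Bundles the force-law constants. Defaults follow the values commonly used
#' with the social forces model's high-density contact extension: a radial
#' (body) force constant `k_radial`, a sliding-friction constant
#' `kappa_friction`, a normal damping constant `c_damp`, and the
#' psychological repulsion magnitude/range `A_social`, `B_social`. All are
#' configurable; every value must be strictly positive.
#'
#' @param k_radial Radial force constant, kg s^-2.
#' @param kappa_friction Sliding friction constant, kg m^-1 s^-1.
#' @param c_damp Damping constant, kg s^-1.
#' @param A_social Psychological repulsion magnitude, N.
#' @param B_social Psychological repulsion range, m.
#' @param v_max Hard speed clamp, m s^-1.
#' @param speed_floor Below this speed the heading is carried over, m s^-1.
#' @param cutoff Engine interaction cutoff, m (social force beyond it is
#'   negligible at the default constants; contact terms always lie inside it).
#' @return A list of class `crush_force_constants`.
#' @export
force_constants <- function(k_radial = 1.2e5, kappa_friction = 2.4e5,
                            c_damp = 500, A_social = 2000, B_social = 0.08,
                            v_max = 5, speed_floor = 0.05, cutoff = 2.0) {
  fc <- list(k_radial = k_radial, kappa_friction = kappa_friction,
             c_damp = c_damp, A_social = A_social, B_social = B_social,
             v_max = v_max, speed_floor = speed_floor, cutoff = cutoff)
  stopifnot(all(vapply(fc, function(x) is.numeric(x) && length(x) == 1 && x > 0, TRUE)))
  structure(fc, class = "crush_force_constants")
}

#' Create an agent record
#'
#' One simulated pedestrian: a circular body of radius `radius` and mass
#' `mass`, relaxing towards its desired speed `v0` over time `tau`.
#'
#' @param id Integer id.
#' @param x,y Position, m.
#' @param vx,vy Velocity, m s^-1.
#' @param theta Heading, radians in (-pi, pi].
#' @param radius Body radius, m.
#' @param mass Mass, kg.
#' @param v0 Desired speed, m s^-1.
#' @param tau Relaxation time, s.
#' @param spawn_time Time the agent entered the arena, s.
#' @param target_exit Target exit id or `NA`.
#' @return A one-row tibble.
#' @export
agent <- function(id, x, y, vx = 0, vy = 0, theta = 0, radius = 0.27,
                  mass = 75, v0 = 1.25, tau = 0.5, spawn_time = 0,
                  target_exit = NA_character_) {
  stopifnot(radius > 0, mass > 0, v0 >= 0, tau > 0, is.finite(theta))
  tibble::tibble(id = as.integer(id), x = x, y = y, vx = vx, vy = vy,
                 theta = theta, radius = radius, mass = mass, v0 = v0,
                 tau = tau, spawn_time = spawn_time, target_exit = target_exit)
}

# Deterministic pseudo-random unit vector for coincident centres, derived
# from the (ordered) id pair so the fallback is reproducible.
coincident_direction <- function(id_i, id_j) {
  h <- sin(id_i * 12.9898 + id_j * 78.233) * 43758.5453
  ang <- 2 * pi * (h - floor(h))
  c(cos(ang), sin(ang))
}

#' Driving force towards a goal
#'
#' The relaxation term of the social forces model:
#' `m (v0 * e_goal - v) / tau`, where `e_goal` is the unit vector from the
#' agent towards `goal_point`. With a coincident goal (and `v0 > 0`) the
#' direction is undefined and the force degrades to pure braking.
#'
#' @param ag One-row agent tibble (see [agent()]).
#' @param goal_point Numeric length-2 goal, m.
#' @return Numeric length-2 force, N.
#' @export
driving_force <- function(ag, goal_point) {
  dx <- goal_point[1] - ag$x
  dy <- goal_point[2] - ag$y
  d <- sqrt(dx^2 + dy^2)
  if (d < 1e-12) {
    e <- c(0, 0)
  } else {
    e <- c(dx, dy) / d
  }
  ag$mass * (ag$v0 * e - c(ag$vx, ag$vy)) / ag$tau
}

#' Psychological repulsion between two agents
#'
#' The non-contact component of agent-agent interaction:
#' `A_social * exp((r_ij - d_ij) / B_social) * n_ij`, with `n_ij` the unit
#' vector from j to i, `d_ij` the centre distance and `r_ij` the combined
#' radii. Strictly decreasing in distance; exactly antisymmetric in its
#' arguments.
#'
#' @param ai,aj One-row agent tibbles.
#' @param fc A [force_constants()] object.
#' @return Numeric length-2 force on `ai`, N.
#' @export
social_repulsion <- function(ai, aj, fc = force_constants()) {
  dx <- ai$x - aj$x
  dy <- ai$y - aj$y
  d <- sqrt(dx^2 + dy^2)
  rij <- ai$radius + aj$radius
  if (d < 1e-12) {
    n <- coincident_direction(min(ai$id, aj$id), max(ai$id, aj$id))
    if (ai$id > aj$id) n <- -n
  } else {
    n <- c(dx, dy) / d
  }
  fc$A_social * exp((rij - d) / fc$B_social) * n
}

#' Physical contact force between two agents
#'
#' Active only in contact (`d_ij < r_ij`, the centre distance below the
#' combined radii); zero otherwise. In contact the force on i is
#' `(k_radial * (r_ij - d_ij)) * n_ij` (radial restoring), minus
#' `c_damp * ((v_i - v_j) . n_ij) * n_ij` (dissipative normal damping,
#' proportional to the difference in normal velocities), plus
#' `kappa_friction * (r_ij - d_ij) * ((v_j - v_i) . t_ij) * t_ij`
#' (sliding friction), where `n_ij` points from j to i and `t_ij` is its
#' +90-degree rotation. The pair force is exactly antisymmetric.
#'
#' @inheritParams social_repulsion
#' @return Numeric length-2 force on `ai`, N.
#' @export
contact_force_pair <- function(ai, aj, fc = force_constants()) {
  dx <- ai$x - aj$x
  dy <- ai$y - aj$y
  d <- sqrt(dx^2 + dy^2)
  rij <- ai$radius + aj$radius
  if (d >= rij) return(c(0, 0))
  if (d < 1e-12) {
    n <- coincident_direction(min(ai$id, aj$id), max(ai$id, aj$id))
    if (ai$id > aj$id) n <- -n
  } else {
    n <- c(dx, dy) / d
  }
  tg <- c(-n[2], n[1])
  overlap <- rij - d
  dvx <- aj$vx - ai$vx
  dvy <- aj$vy - ai$vy
  dv_n <- dvx * n[1] + dvy * n[2]   # (v_j - v_i) . n
  dv_t <- dvx * tg[1] + dvy * tg[2] # (v_j - v_i) . t
  (fc$k_radial * overlap + fc$c_damp * dv_n) * n +
    fc$kappa_friction * overlap * dv_t * tg
}

#' Contact force from a wall segment
#'
#' The wall is treated as a zero-radius, zero-velocity individual located at
#' the nearest wall point: the same contact law (same constants) applies,
#' with the outward normal from [closest_point_on_segment()]. Zero whenever
#' the centre-to-wall distance is at least the agent's radius.
#'
#' @param ag One-row agent tibble.
#' @param seg Numeric length-4 segment `c(x1, y1, x2, y2)`.
#' @param fc A [force_constants()] object.
#' @return Numeric length-2 force, N.
#' @export
wall_contact_force <- function(ag, seg, fc = force_constants()) {
  cp <- closest_point_on_segment(c(ag$x, ag$y), seg[1:2], seg[3:4])
  d <- cp$distance
  if (d >= ag$radius) return(c(0, 0))
  n <- cp$normal
  tg <- c(-n[2], n[1])
  overlap <- ag$radius - d
  dv_n <- (-ag$vx) * n[1] + (-ag$vy) * n[2]
  dv_t <- (-ag$vx) * tg[1] + (-ag$vy) * tg[2]
  (fc$k_radial * overlap + fc$c_damp * dv_n) * n +
    fc$kappa_friction * overlap * dv_t * tg
}

#' Per-agent contact-force magnitudes for a population snapshot
#'
#' Computes, for every agent, the contact force suffered this instant: the
#' summation of the contact contributions from other individuals and from
#' structural components. Two statistics are returned per agent: the norm of
#' the net contact-force vector, and the scalar sum of the individual contact
#' magnitudes (compression does not cancel even when the net vector does).
#' Social (non-contact) and driving forces are excluded. This is a direct
#' (O(n^2)) reference computation used for cross-checking the engine.
#'
#' @param agents Agent tibble (rows as from [agent()]).
#' @param arena A `crush_arena`, or `NULL` to ignore walls.
#' @param fc A [force_constants()] object.
#' @param time Simulation time (determines which door segments are solid).
#' @return Tibble with columns `id, net_N, scalar_N`.
#' @export
contact_magnitudes <- function(agents, arena = NULL, fc = force_constants(), time = 0) {
  n <- nrow(agents)
  fx <- numeric(n); fy <- numeric(n); sc <- numeric(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        f <- contact_force_pair(agents[i, ], agents[j, ], fc)
        if (f[1] != 0 || f[2] != 0) {
          fx[i] <- fx[i] + f[1]; fy[i] <- fy[i] + f[2]
          fx[j] <- fx[j] - f[1]; fy[j] <- fy[j] - f[2]
          m <- sqrt(sum(f^2))
          sc[i] <- sc[i] + m; sc[j] <- sc[j] + m
        }
      }
    }
  }
  if (!is.null(arena)) {
    segs <- arena_wall_segments(arena)
    solid <- !(segs$gap_from <= time & time < segs$gap_until)
    segs <- segs[solid, , drop = FALSE]
    for (i in seq_len(n)) {
      for (k in seq_len(nrow(segs))) {
        f <- wall_contact_force(agents[i, ], as.numeric(segs[k, 1:4]), fc)
        if (f[1] != 0 || f[2] != 0) {
          fx[i] <- fx[i] + f[1]; fy[i] <- fy[i] + f[2]
          sc[i] <- sc[i] + sqrt(sum(f^2))
        }
      }
    }
  }
  tibble::tibble(id = agents$id, net_N = sqrt(fx^2 + fy^2), scalar_N = sc)
}
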