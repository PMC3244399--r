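#' Construct a wall segment
#'
#' A wall is a straight, impassable 2-D segment in metres, in plan-view
#' coordinates (origin at the arena's south-west corner, x east, y north).
#'
#' @param x1,y1,x2,y2 Segment endpoints in metres.
#' @return A one-row tibble with columns `x1, y1, x2, y2`.
#' @export
wall <- function(x1, y1, x2, y2) {
  stopifnot(is.finite(x1), is.finite(y1), is.finite(x2), is.finite(y2))
  if (x1 == x2 && y1 == y2) {
    stop("wall(): degenerate zero-length segment", call. = FALSE)
  }
  tibble::tibble(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

#' Construct a convex polygonal obstacle
#'
#' Obstacles are convex polygons; for force purposes they are treated as a
#' closed cycle of wall segments.
#'
#' @param vertices A numeric matrix (or data frame) with two columns (x, y in
#'   metres) and at least 3 rows, listing the polygon boundary in order.
#' @return An object of class `crush_obstacle` (a vertex matrix).
#' @export
obstacle <- function(vertices) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  stopifnot(ncol(v) == 2, nrow(v) >= 3, all(is.finite(v)))
  if (!is_convex_polygon(v)) {
    stop("obstacle(): vertices must describe a convex, non-self-intersecting polygon",
         call. = FALSE)
  }
  structure(v, class = c("crush_obstacle", "matrix", "array"))
}

# Cross-product convexity check; collinear runs are tolerated.
is_convex_polygon <- function(v) {
  n <- nrow(v)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[i %% n + 1, ]
    c <- v[(i + 1) %% n + 1, ]
    cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cr) < 1e-12) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

#' Construct an exit door
#'
#' An exit is a passable opening on a wall (or on the arena boundary) through
#' which agents leave. Outside its open window `[open_from, open_until)` the
#' segment is solid wall: agents can neither pass nor be absorbed.
#'
#' @param id Character label, unique within an arena.
#' @param x1,y1,x2,y2 Door segment endpoints in metres.
#' @param open_from,open_until Open window in seconds (default: always open).
#' @return A one-row tibble.
#' @export
exit_door <- function(id, x1, y1, x2, y2, open_from = 0, open_until = Inf) {
  stopifnot(is.character(id), length(id) == 1L, open_from < open_until)
  if (x1 == x2 && y1 == y2) stop("exit_door(): zero-length segment", call. = FALSE)
  tibble::tibble(id = id, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 open_from = open_from, open_until = open_until)
}

#' Construct an entrance
#'
#' An entrance is a boundary segment through which new agents are injected at
#' `inflow_rate` agents per second. The segment itself remains solid (agents
#' are placed just inside it); `nx, ny` is the inward unit normal used for the
#' placement offset.
#'
#' @param id Character label.
#' @param x1,y1,x2,y2 Segment endpoints in metres.
#' @param inflow_rate Agents per second, >= 0.
#' @param nx,ny Inward unit normal of the entrance segment.
#' @return A one-row tibble.
#' @export
entrance <- function(id, x1, y1, x2, y2, inflow_rate, nx, ny) {
  stopifnot(is.character(id), length(id) == 1L, inflow_rate >= 0)
  nn <- sqrt(nx^2 + ny^2)
  stopifnot(nn > 0)
  tibble::tibble(id = id, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                 inflow_rate = inflow_rate, nx = nx / nn, ny = ny / nn)
}

#' Assemble an arena
#'
#' An arena is an axis-aligned bounding rectangle plus walls, convex
#' obstacles, exits and entrances. The four boundary edges are solid walls
#' except where exit segments lying on them punch openings.
#'
#' @param bounds Numeric vector `c(xmin, ymin, xmax, ymax)` in metres.
#' @param walls Tibble of wall segments (rows from [wall()]), or `NULL`.
#' @param obstacles List of [obstacle()] objects.
#' @param exits Tibble of exits (rows from [exit_door()]).
#' @param entrances Tibble of entrances (rows from [entrance()]), or `NULL`.
#' @return An object of class `crush_arena`.
#' @export
arena <- function(bounds, walls = NULL, obstacles = list(), exits, entrances = NULL) {
  stopifnot(length(bounds) == 4, bounds[1] < bounds[3], bounds[2] < bounds[4])
  if (is.null(walls)) walls <- wall(bounds[1], bounds[2], bounds[1], bounds[2] + 1)[0, ]
  if (is.null(entrances)) entrances <- entrance("e", 0, 0, 1, 0, 0, 0, 1)[0, ]
  stopifnot(nrow(exits) >= 1, !anyDuplicated(exits$id))
  a <- structure(
    list(bounds = as.numeric(bounds), walls = tibble::as_tibble(walls),
         obstacles = obstacles, exits = tibble::as_tibble(exits),
         entrances = tibble::as_tibble(entrances)),
    class = "crush_arena")
  validate_arena(a)
  a
}

#' @export
print.crush_arena <- function(x, ...) {
  cat(sprintf("<crush_arena> %.3g m x %.3g m, %d wall(s), %d obstacle(s), %d exit(s), %d entrance(s)\n",
              x$bounds[3] - x$bounds[1], x$bounds[4] - x$bounds[2],
              nrow(x$walls), length(x$obstacles), nrow(x$exits), nrow(x$entrances)))
  invisible(x)
}

validate_arena <- function(a) {
  b <- a$bounds
  inb <- function(x, y) x >= b[1] - 1e-9 & x <= b[3] + 1e-9 & y >= b[2] - 1e-9 & y <= b[4] + 1e-9
  segs <- rbind(
    as.matrix(a$walls[, c("x1", "y1", "x2", "y2")]),
    as.matrix(a$exits[, c("x1", "y1", "x2", "y2")]),
    as.matrix(a$entrances[, c("x1", "y1", "x2", "y2")]))
  if (nrow(segs) && !all(inb(segs[, 1], segs[, 2]) & inb(segs[, 3], segs[, 4]))) {
    stop("arena(): geometry outside bounds", call. = FALSE)
  }
  for (ob in a$obstacles) {
    if (!all(inb(ob[, 1], ob[, 2]))) stop("arena(): obstacle outside bounds", call. = FALSE)
  }
  invisible(a)
}

#' Closest point on a segment
#'
#' Returns the point on segment `(a1, a2)` nearest to `p`, the Euclidean
#' distance, and the outward unit normal pointing from the segment towards
#' `p`. Support primitive for the wall contact force.
#'
#' @param p Numeric length-2 query point (metres).
#' @param a1,a2 Numeric length-2 segment endpoints.
#' @return List with `point` (length-2), `distance` (scalar, m), and `normal`
#'   (length-2 unit vector).
#' @export
closest_point_on_segment <- function(p, a1, a2) {
  d <- a2 - a1
  len2 <- sum(d^2)
  if (len2 == 0) stop("closest_point_on_segment(): degenerate segment", call. = FALSE)
  t <- sum((p - a1) * d) / len2
  t <- min(1, max(0, t))
  q <- a1 + t * d
  delta <- p - q
  dist <- sqrt(sum(delta^2))
  if (dist > 1e-12) {
    nrm <- delta / dist
  } else {
    # On-segment query: any consistent side; use the left-hand normal.
    nrm <- c(-d[2], d[1]) / sqrt(len2)
  }
  list(point = q, distance = dist, normal = nrm)
}

#' Nearest known open exit
#'
#' Route choice: among the exits the agent knows about that are open at
#' `time`, pick the one whose segment midpoint is nearest (Euclidean).
#' Ties are broken by the lexicographically smallest exit id so replicate
#' runs are reproducible. Line-of-sight is deliberately not modelled;
#' obstacle avoidance emerges from the repulsion forces.
#'
#' @param position Numeric length-2 position (metres).
#' @param known_exits Character vector of known exit ids.
#' @param exits Exit tibble (as in an arena).
#' @param time Simulation time in seconds.
#' @return The chosen exit id, or `NA_character_` if no known exit is open.
#' @export
nearest_known_open_exit <- function(position, known_exits, exits, time) {
  cand <- exits[exits$id %in% known_exits &
                  exits$open_from <= time & time < exits$open_until, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_character_)
  mx <- (cand$x1 + cand$x2) / 2
  my <- (cand$y1 + cand$y2) / 2
  d <- sqrt((mx - position[1])^2 + (my - position[2])^2)
  cand <- cand[order(d, cand$id), , drop = FALSE]
  cand$id[1]
}

# Obstacle boundary as a tibble of wall segments.
obstacle_segments <- function(ob) {
  n <- nrow(ob)
  j <- c(2:n, 1)
  tibble::tibble(x1 = ob[, 1], y1 = ob[, 2], x2 = ob[j, 1], y2 = ob[j, 2])
}

# Split `seg` (x1,y1,x2,y2) by removing the collinear sub-segment `cut`.
# Returns a matrix of remaining sub-segments (0, 1 or 2 rows).
punch_segment <- function(seg, cut) {
  a1 <- seg[1:2]; a2 <- seg[3:4]
  d <- a2 - a1
  len2 <- sum(d^2)
  proj <- function(p) sum((p - a1) * d) / len2
  # Collinearity: both cut endpoints within tolerance of the carrier line.
  offline <- function(p) abs((p[1] - a1[1]) * d[2] - (p[2] - a1[2]) * d[1]) / sqrt(len2)
  c1 <- cut[1:2]; c2 <- cut[3:4]
  if (offline(c1) > 1e-6 || offline(c2) > 1e-6) return(matrix(seg, nrow = 1))
  t1 <- proj(c1); t2 <- proj(c2)
  lo <- max(0, min(t1, t2)); hi <- min(1, max(t1, t2))
  if (hi <= lo) return(matrix(seg, nrow = 1))
  out <- NULL
  eps <- 1e-9
  if (lo > eps) out <- rbind(out, c(a1, a1 + lo * d))
  if (hi < 1 - eps) out <- rbind(out, c(a1 + hi * d, a2))
  if (is.null(out)) matrix(numeric(0), ncol = 4) else out
}

#' Solid wall segments of an arena
#'
#' Expands an arena into the flat table of wall segments the physics engine
#' uses: boundary edges with openings punched out at exit segments, explicit
#' walls, obstacle boundary cycles, entrance segments (always solid), and the
#' exit door segments themselves carrying their open windows (a door is solid
#' wall whenever it is not open).
#'
#' @param a A `crush_arena`.
#' @return Tibble with columns `x1, y1, x2, y2, gap_from, gap_until`; the
#'   segment is passable for `gap_from <= t < gap_until` and solid otherwise.
#' @export
arena_wall_segments <- function(a) {
  b <- a$bounds
  edges <- rbind(
    c(b[1], b[2], b[3], b[2]),
    c(b[3], b[2], b[3], b[4]),
    c(b[3], b[4], b[1], b[4]),
    c(b[1], b[4], b[1], b[2]))
  openings <- as.matrix(a$exits[, c("x1", "y1", "x2", "y2")])
  solid <- NULL
  for (i in seq_len(nrow(edges))) {
    pieces <- matrix(edges[i, ], nrow = 1)
    for (k in seq_len(nrow(openings))) {
      pieces <- do.call(rbind, lapply(seq_len(nrow(pieces)), function(r) {
        punch_segment(pieces[r, ], openings[k, ])
      }))
      if (is.null(pieces) || nrow(pieces) == 0) {
        pieces <- matrix(numeric(0), ncol = 4)
        break
      }
    }
    solid <- rbind(solid, pieces)
  }
  extra <- as.matrix(a$walls[, c("x1", "y1", "x2", "y2")])
  # Explicit interior walls may also carry exit openings (club partitions).
  if (nrow(extra)) {
    for (i in seq_len(nrow(extra))) {
      pieces <- matrix(extra[i, ], nrow = 1)
      for (k in seq_len(nrow(openings))) {
        pieces <- do.call(rbind, lapply(seq_len(nrow(pieces)), function(r) {
          punch_segment(pieces[r, ], openings[k, ])
        }))
        if (is.null(pieces) || nrow(pieces) == 0) {
          pieces <- matrix(numeric(0), ncol = 4)
          break
        }
      }
      solid <- rbind(solid, pieces)
    }
  }
  for (ob in a$obstacles) {
    solid <- rbind(solid, as.matrix(obstacle_segments(ob)))
  }
  if (nrow(a$entrances)) {
    solid <- rbind(solid, as.matrix(a$entrances[, c("x1", "y1", "x2", "y2")]))
  }
  solid <- tibble::tibble(x1 = solid[, 1], y1 = solid[, 2],
                          x2 = solid[, 3], y2 = solid[, 4],
                          gap_from = Inf, gap_until = Inf)
  doors <- tibble::tibble(
    x1 = a$exits$x1, y1 = a$exits$y1, x2 = a$exits$x2, y2 = a$exits$y2,
    gap_from = a$exits$open_from, gap_until = a$exits$open_until)
  dplyr::bind_rows(solid, doors)
}
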