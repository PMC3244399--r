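#' Equal-width discretizer specification
#'
#' Defines the histogram granularity for one variable: `n_bins` equal-width
#' bins over `[lo, hi]`, with out-of-range values clamped to the edge bins.
#' For the heading variable set `periodic = TRUE`: values are first wrapped
#' into (-pi, pi] so the bin edges at pi are treated cyclically.
#'
#' @param n_bins Number of bins, >= 2.
#' @param lo,hi Value range; `lo < hi`.
#' @param periodic Wrap values into (-pi, pi] before binning.
#' @return A list of class `crush_discretizer`.
#' @export
discretizer_spec <- function(n_bins = 8, lo, hi, periodic = FALSE) {
  stopifnot(n_bins >= 2, lo < hi)
  structure(list(n_bins = as.integer(n_bins), lo = lo, hi = hi,
                 periodic = isTRUE(periodic)),
            class = "crush_discretizer")
}

#' Discretize values into bin indices
#'
#' @param values Numeric vector; all values must be finite.
#' @param spec A [discretizer_spec()].
#' @return Integer bin indices in `[0, n_bins)` (zero-based, matching the
#'   histogram row/column order).
#' @export
discretize <- function(values, spec) {
  if (any(!is.finite(values))) {
    stop("discretize(): non-finite value", call. = FALSE)
  }
  v <- values
  if (spec$periodic) {
    v <- ((v + pi) %% (2 * pi))
    v <- ifelse(v == 0, 2 * pi, v) - pi  # (-pi, pi]
  }
  w <- (spec$hi - spec$lo) / spec$n_bins
  b <- floor((v - spec$lo) / w)
  pmin(pmax(b, 0), spec$n_bins - 1L)
}

#' Mutual information of a joint count table, in bits
#'
#' The plug-in (histogram) estimator: with empirical probabilities
#' `p(a,b) = n_ab / N`, returns `sum p(a,b) log2( p(a,b) / (p(a) p(b)) )`.
#' Zero-count cells contribute nothing; tiny negative round-off is clipped
#' at zero. Computed through the entropy identity
#' `MI = H(A) + H(B) - H(A,B)` (an independent brute-force double-sum oracle
#' is kept in the test suite).
#'
#' @param counts Non-negative integer matrix of joint counts.
#' @return Mutual information in bits (scalar, >= 0).
#' @export
mi_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  N <- sum(counts)
  if (N < 1) stop("mi_from_counts(): empty histogram", call. = FALSE)
  p <- counts / N
  pr <- rowSums(p)
  pc <- colSums(p)
  ent <- function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  mi <- ent(pr) + ent(pc) - ent(p)
  mi <- max(0, mi)
  # estimator sanity: MI bounded by each marginal entropy (up to round-off)
  stopifnot(mi <= min(ent(pr), ent(pc)) + 1e-9)
  mi
}

#' Expected plug-in bias of histogram MI under independence
#'
#' The plug-in estimator is positively biased by approximately
#' `(B - 1)^2 / (2 N ln 2)` bits at sample size `N` with `B` bins per margin;
#' this is the mean of the chi-square null and bounds the "zero" of any
#' independence test on finite samples.
#'
#' @param n_bins Bins per margin.
#' @param n_samples Number of pooled pair samples.
#' @return Bias in bits.
#' @export
mi_bias_bound <- function(n_bins, n_samples) {
  (n_bins - 1)^2 / (2 * n_samples * log(2))
}

#' Null quantile of histogram MI under independence
#'
#' Under independence, `2 N ln(2) MI` is asymptotically chi-square with
#' `(B - 1)^2` degrees of freedom; this returns the corresponding upper
#' quantile of MI in bits, a calibrated threshold for "indistinguishable
#' from independent".
#'
#' @inheritParams mi_bias_bound
#' @param conf Confidence level (default 0.999).
#' @return MI threshold in bits.
#' @export
mi_null_quantile <- function(n_bins, n_samples, conf = 0.999) {
  stats::qchisq(conf, df = (n_bins - 1)^2) / (2 * n_samples * log(2))
}

# Pooled ordered-pair joint histogram from a steps-by-bins occupancy count
# matrix W: at each step with occupancy c, the (i, j), i != j ordered pairs
# contribute c_a c_b to off-diagonal cells and c_a (c_a - 1) to the
# diagonal; summing over steps gives crossprod(W) - diag(colSums(W)).
pair_joint_from_counts <- function(W) {
  W <- as.matrix(W)
  J <- crossprod(W)
  diag(J) <- diag(J) - colSums(W)
  J
}

#' Pair sampling policy
#'
#' All ordered pairs of distinct agents are pooled by default. Above
#' `max_pairs` pooled samples per window the joint histogram is uniformly
#' subsampled (multinomially, using the session RNG) to bound cost at large
#' populations.
#'
#' @param max_pairs Pair-count budget per window (default 2e6).
#' @return A list of class `crush_pair_policy`.
#' @export
pair_policy <- function(max_pairs = 2e6) {
  stopifnot(max_pairs >= 1)
  structure(list(max_pairs = max_pairs), class = "crush_pair_policy")
}

apply_pair_policy <- function(J, policy) {
  N <- sum(J)
  if (is.null(policy) || N <= policy$max_pairs) return(J)
  probs <- as.vector(J) / N
  sub <- stats::rmultinom(1, size = policy$max_pairs, prob = probs)
  matrix(sub, nrow = nrow(J))
}

#' Pairwise population mutual information of one variable
#'
#' The order parameter underlying the crush detector. For each time step in
#' the window the variable (`x`, `y` or `theta`) is discretized for every
#' agent present; every ordered pair of distinct agents contributes one
#' `(bin_i, bin_j)` sample, and all samples over the whole window are pooled
#' into a single joint histogram whose plug-in MI is returned. Ordered pairs
#' make the joint symmetric, so the reading does not depend on pair
#' orientation.
#'
#' @param traj Trajectory tibble with columns `step`, and the variable column
#'   (`x_m`, `y_m` or `theta_rad`) plus `agent_id`.
#' @param variable One of `"x"`, `"y"`, `"theta"`.
#' @param spec A [discretizer_spec()] for the variable.
#' @param policy A [pair_policy()] (or `NULL` for no budget).
#' @param mode `"pooled"` (default) pools all window pairs into one
#'   histogram; `"average_per_step"` computes a per-step MI and averages.
#' @return MI in bits.
#' @export
pairwise_population_mi <- function(traj, variable = c("x", "y", "theta"),
                                   spec, policy = pair_policy(),
                                   mode = c("pooled", "average_per_step")) {
  variable <- match.arg(variable)
  mode <- match.arg(mode)
  col <- switch(variable, x = "x_m", y = "y_m", theta = "theta_rad")
  if (nrow(traj) == 0) stop("pairwise_population_mi(): empty window", call. = FALSE)
  W <- occupancy_counts(traj$step, traj[[col]], spec)
  if (all(rowSums(W) < 2)) {
    stop("pairwise_population_mi(): fewer than 2 agents at every step",
         call. = FALSE)
  }
  mi_from_occupancy(W, policy, mode)
}

# steps-by-bins occupancy matrix from per-row (step, value) observations
occupancy_counts <- function(step, value, spec) {
  b <- discretize(value, spec)
  steps <- sort(unique(step))
  W <- matrix(0L, nrow = length(steps), ncol = spec$n_bins)
  si <- match(step, steps)
  for (k in seq_along(b)) W[si[k], b[k] + 1L] <- W[si[k], b[k] + 1L] + 1L
  W
}

mi_from_occupancy <- function(W, policy, mode) {
  if (mode == "pooled") {
    J <- pair_joint_from_counts(W)
    if (sum(J) < 1) stop("undefined MI: no agent pairs in window", call. = FALSE)
    J <- apply_pair_policy(J, policy)
    mi_from_counts(J)
  } else {
    ok <- rowSums(W) >= 2
    if (!any(ok)) stop("undefined MI: no agent pairs in window", call. = FALSE)
    vals <- apply(W[ok, , drop = FALSE], 1, function(cc) {
      mi_from_counts(pair_joint_from_counts(matrix(cc, nrow = 1)))
    })
    mean(vals)
  }
}

#' One mutual-information reading from a window of trajectory steps
#'
#' Applies [pairwise_population_mi()] to x, y and heading over a window of
#' consecutive steps (100 steps = one reading per second at the default
#' dt = 0.01 s) and averages the three components into `mi_mean`. A reading
#' is flagged invalid when the mean population over the window falls below
#' `n_min`; invalid readings carry `NA` MI values.
#'
#' @param window Trajectory tibble covering the window (columns `step`,
#'   `agent_id`, `x_m`, `y_m`, `theta_rad`).
#' @param specs Named list of discretizers with elements `x`, `y`, `theta`.
#' @param n_min Minimum mean population for a valid reading (default 10).
#' @param policy,mode Passed to [pairwise_population_mi()].
#' @param time Time stamp to attach, s (default: max step time seen).
#' @return One-row tibble: `time_s, mi_x_bits, mi_y_bits, mi_theta_bits,
#'   mi_mean_bits, n_agents, valid`.
#' @export
mi_reading <- function(window, specs, n_min = 10, policy = pair_policy(),
                       mode = "pooled", time = NA_real_) {
  steps <- unique(window$step)
  n_mean <- nrow(window) / max(1L, length(steps))
  if (is.na(time)) {
    time <- if ("time_s" %in% names(window)) max(window$time_s) else max(window$step)
  }
  if (n_mean < n_min) {
    return(tibble::tibble(time_s = time, mi_x_bits = NA_real_,
                          mi_y_bits = NA_real_, mi_theta_bits = NA_real_,
                          mi_mean_bits = NA_real_, n_agents = n_mean,
                          valid = FALSE))
  }
  mx <- pairwise_population_mi(window, "x", specs$x, policy, mode)
  my <- pairwise_population_mi(window, "y", specs$y, policy, mode)
  mt <- pairwise_population_mi(window, "theta", specs$theta, policy, mode)
  tibble::tibble(time_s = time, mi_x_bits = mx, mi_y_bits = my,
                 mi_theta_bits = mt, mi_mean_bits = mean(c(mx, my, mt)),
                 n_agents = n_mean, valid = TRUE)
}

#' Detector options
#'
#' @param n_bins Bins per variable (default 8; coarse binning controls
#'   plug-in bias at crowd-sized samples).
#' @param n_min Minimum mean population for a valid reading.
#' @param steps_per_reading Window length in steps (100 steps = 1 s at
#'   dt = 0.01 s).
#' @param mode `"pooled"` or `"average_per_step"` (see
#'   [pairwise_population_mi()]).
#' @param max_pairs Pair budget per window.
#' @return A list of class `crush_detector_options`.
#' @export
detector_options <- function(n_bins = 8, n_min = 10, steps_per_reading = 100,
                             mode = c("pooled", "average_per_step"),
                             max_pairs = 2e6) {
  mode <- match.arg(mode)
  structure(list(n_bins = as.integer(n_bins), n_min = n_min,
                 steps_per_reading = as.integer(steps_per_reading),
                 mode = mode, max_pairs = max_pairs),
            class = "crush_detector_options")
}

mi_specs_for_bounds <- function(bounds, n_bins) {
  list(x = discretizer_spec(n_bins, bounds[1], bounds[3]),
       y = discretizer_spec(n_bins, bounds[2], bounds[4]),
       theta = discretizer_spec(n_bins, -pi, pi, periodic = TRUE))
}

#' Mutual-information series of a trajectory table
#'
#' Slices a trajectory into consecutive windows of `steps_per_reading` steps
#' and emits one [mi_reading()] per window — the per-second MI order
#' parameter of the recorded population.
#'
#' @param traj Trajectory tibble (simulator dialect: `step, time_s, agent_id,
#'   x_m, y_m, vx, vy, theta_rad, contact_force_N`).
#' @param bounds Arena bounds `c(xmin, ymin, xmax, ymax)` defining the x/y
#'   discretizer ranges.
#' @param opts A [detector_options()].
#' @return Tibble of readings, one row per full window.
#' @export
mi_series <- function(traj, bounds, opts = detector_options()) {
  specs <- mi_specs_for_bounds(bounds, opts$n_bins)
  steps <- sort(unique(traj$step))
  k <- length(steps) %/% opts$steps_per_reading
  out <- vector("list", k)
  for (w in seq_len(k)) {
    sw <- steps[((w - 1) * opts$steps_per_reading + 1):(w * opts$steps_per_reading)]
    win <- traj[traj$step %in% sw, , drop = FALSE]
    out[[w]] <- mi_reading(win, specs, n_min = opts$n_min,
                           policy = pair_policy(opts$max_pairs),
                           mode = opts$mode,
                           time = max(win$time_s))
  }
  dplyr::bind_rows(out)
}

# MI series from the engine's per-step occupancy count matrices (one row per
# step). Identical estimator to mi_series(), bypassing row-level tables.
mi_series_from_counts <- function(counts_x, counts_y, counts_th, n_agents,
                                  times, opts) {
  spr <- opts$steps_per_reading
  k <- nrow(counts_x) %/% spr
  out <- vector("list", k)
  policy <- pair_policy(opts$max_pairs)
  for (w in seq_len(k)) {
    rows <- ((w - 1) * spr + 1):(w * spr)
    n_mean <- mean(n_agents[rows])
    tm <- times[rows[spr]]
    if (n_mean < opts$n_min) {
      out[[w]] <- tibble::tibble(time_s = tm, mi_x_bits = NA_real_,
                                 mi_y_bits = NA_real_, mi_theta_bits = NA_real_,
                                 mi_mean_bits = NA_real_, n_agents = n_mean,
                                 valid = FALSE)
    } else {
      mx <- mi_from_occupancy(counts_x[rows, , drop = FALSE], policy, opts$mode)
      my <- mi_from_occupancy(counts_y[rows, , drop = FALSE], policy, opts$mode)
      mt <- mi_from_occupancy(counts_th[rows, , drop = FALSE], policy, opts$mode)
      out[[w]] <- tibble::tibble(time_s = tm, mi_x_bits = mx, mi_y_bits = my,
                                 mi_theta_bits = mt,
                                 mi_mean_bits = mean(c(mx, my, mt)),
                                 n_agents = n_mean, valid = TRUE)
    }
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
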