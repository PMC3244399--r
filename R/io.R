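#' Read and write trajectory tables
#'
#' The columnar trajectory dialect shared by the simulator, the fixtures and
#' the analysis functions: one row per agent per recorded step, columns
#' `step, time_s, agent_id, x_m, y_m, vx, vy, theta_rad, contact_force_N`.
#'
#' @param traj A trajectory tibble.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("step", "time_s", "agent_id", "x_m", "y_m", "vx", "vy",
            "theta_rad", "contact_force_N")
  stopifnot(all(cols %in% names(traj)))
  readr::write_csv(traj[, cols], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    step = readr::col_integer(), time_s = readr::col_double(),
    agent_id = readr::col_integer(), x_m = readr::col_double(),
    y_m = readr::col_double(), vx = readr::col_double(),
    vy = readr::col_double(), theta_rad = readr::col_double(),
    contact_force_N = readr::col_double()))
}

#' Write per-second MI or force series
#'
#' @param series A readings tibble (from `mi_series()`, `force_series()` or
#'   a `crush_sim`).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}
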