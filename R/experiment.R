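#' Run a replicate ensemble of a scenario
#'
#' Replicate `i` runs with seed `base_seed + i - 1` (exact reproducibility:
#' the same spec and base seed give a bit-identical ensemble). Per-second MI
#' and force readings and the leaving profiles are collected per replicate,
#' and pointwise mean and standard error over valid readings are computed on
#' the common per-second grid.
#'
#' @param spec A `crush_scenario`.
#' @param n Number of replicates, >= 1.
#' @param base_seed Integer base seed.
#' @param ... Passed on to [simulate_scenario()].
#' @return A list of class `crush_ensemble`: `replicates` (tibble of nested
#'   per-replicate series), `mi_aggregate`, `force_aggregate`, `leaving`,
#'   `label`, `seeds`.
#' @export
run_replicates <- function(spec, n, base_seed = 1L, ...) {
  stopifnot(n >= 1)
  seeds <- base_seed + seq_len(n) - 1L
  runs <- lapply(seeds, function(s) simulate_scenario(spec, seed = s, ...))
  reps <- tibble::tibble(
    replicate = seq_len(n), seed = seeds,
    mi = lapply(runs, `[[`, "mi"),
    force = lapply(runs, `[[`, "force"),
    leaving = lapply(runs, `[[`, "leaving"),
    spawned = vapply(runs, function(r) r$counters$spawned, 1L),
    exited = vapply(runs, function(r) r$counters$exited, 1L))
  mi_long <- dplyr::bind_rows(reps$mi, .id = "replicate")
  force_long <- dplyr::bind_rows(reps$force, .id = "replicate")
  mi_agg <- mi_long |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      mi_se_bits = stats::sd(.data$mi_mean_bits) / sqrt(dplyr::n()),
      mi_mean_bits = mean(.data$mi_mean_bits),
      mi_x_bits = mean(.data$mi_x_bits), mi_y_bits = mean(.data$mi_y_bits),
      mi_theta_bits = mean(.data$mi_theta_bits),
      n_replicates = dplyr::n(), .groups = "drop")
  force_agg <- force_long |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(
      force_se_N = stats::sd(.data$mean_force_N) / sqrt(dplyr::n()),
      mean_force_N = mean(.data$mean_force_N),
      mean_scalar_force_N = mean(.data$mean_scalar_force_N),
      max_agent_force_N = max(.data$max_agent_force_N),
      n_agents = mean(.data$n_agents),
      n_replicates = dplyr::n(), .groups = "drop")
  structure(list(replicates = reps, mi_aggregate = mi_agg,
                 force_aggregate = force_agg, label = spec$label,
                 seeds = seeds, spec_hash = scenario_hash(spec)),
            class = "crush_ensemble")
}

# Stable content hash of a scenario spec (used in run manifests).
scenario_hash <- function(spec) {
  js <- jsonlite::serializeJSON(spec[c("duration", "initial_agents",
                                       "placement", "agent_params",
                                       "knowledge", "fallback_exit", "label")])
  sprintf("%08x", sum(utf8ToInt(as.character(js)) *
                        seq_along(utf8ToInt(as.character(js)))) %% .Machine$integer.max)
}

#' @export
print.crush_ensemble <- function(x, ...) {
  cat(sprintf("<crush_ensemble> '%s': %d replicates (seeds %d..%d)\n",
              x$label, nrow(x$replicates), min(x$seeds), max(x$seeds)))
  invisible(x)
}

#' @rdname tidy_crush
#' @export
tidy.crush_ensemble <- function(x, ...) {
  dplyr::left_join(x$mi_aggregate, x$force_aggregate, by = "time_s",
                   suffix = c("", "_force"))
}

#' @rdname tidy_crush
#' @export
glance.crush_ensemble <- function(x, ...) {
  tibble::tibble(
    scenario = x$label, n_replicates = nrow(x$replicates),
    mean_mi_bits = mean(x$mi_aggregate$mi_mean_bits),
    mean_force_N = mean(x$force_aggregate$mean_force_N),
    total_exited = sum(x$replicates$exited))
}

#' Pearson correlation with two-tailed p-value
#'
#' A simple linear correlation test between two aligned series: Pearson's r
#' and the two-tailed p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length; pairs with `NA` in either are
#'   dropped; at least 3 complete pairs and non-zero variance are required.
#' @return A list of class `crush_correlation` with `r`, `p_two_tailed`,
#'   `n_points`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_correlation(): fewer than 3 complete pairs",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_correlation(): zero variance, correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_two_tailed = ct$p.value,
                 n_points = length(x)),
            class = "crush_correlation")
}

#' @export
print.crush_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, two-tailed p = %.3g, n = %d\n",
              x$r, x$p_two_tailed, x$n_points))
  invisible(x)
}

#' @rdname tidy_crush
#' @export
tidy.crush_correlation <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p_two_tailed, n = x$n_points,
                 method = "pearson", alternative = "two.sided")
}

#' @rdname tidy_crush
#' @export
glance.crush_correlation <- function(x, ...) tidy(x)

#' Correlate MI and force readings of an ensemble
#'
#' Pools the per-second (MI, force) reading pairs across all replicates of
#' an ensemble (invalid MI readings dropped pairwise) and runs
#' [pearson_correlation()]. Per-replicate correlations are attached for
#' reference.
#'
#' @param ensemble A `crush_ensemble`.
#' @return A `crush_correlation` with an extra `per_replicate` tibble.
#' @export
correlate_mi_force <- function(ensemble) {
  pairs <- mi_force_pairs(ensemble)
  res <- pearson_correlation(pairs$mi_mean_bits, pairs$mean_force_N)
  per_rep <- pairs |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(r = tryCatch(
      pearson_correlation(.data$mi_mean_bits, .data$mean_force_N)$r,
      error = function(e) NA_real_), .groups = "drop")
  res$per_replicate <- per_rep
  res
}

# pooled per-second (MI, force) reading pairs across replicates
mi_force_pairs <- function(ensemble) {
  reps <- ensemble$replicates
  dplyr::bind_rows(lapply(seq_len(nrow(reps)), function(i) {
    mi <- reps$mi[[i]]
    fo <- reps$force[[i]]
    dplyr::inner_join(mi[mi$valid, c("time_s", "mi_mean_bits")],
                      fo[, c("time_s", "mean_force_N")], by = "time_s") |>
      dplyr::mutate(replicate = i)
  }))
}

#' Per-exit leaving profiles of an ensemble
#'
#' @param ensemble A `crush_ensemble`.
#' @param by Time bin width for the cumulative profile, s.
#' @return Tibble `replicate, exit_id, time_s, cumulative_exited`.
#' @export
leaving_profiles <- function(ensemble, by = 1) {
  reps <- ensemble$replicates
  dplyr::bind_rows(lapply(seq_len(nrow(reps)), function(i) {
    lv <- reps$leaving[[i]]
    if (nrow(lv) == 0) return(NULL)
    lv |>
      dplyr::mutate(time_s = ceiling(.data$time_s / by) * by) |>
      dplyr::count(.data$exit_id, .data$time_s) |>
      dplyr::group_by(.data$exit_id) |>
      dplyr::arrange(.data$time_s, .by_group = TRUE) |>
      dplyr::mutate(cumulative_exited = cumsum(.data$n), replicate = i) |>
      dplyr::ungroup() |>
      dplyr::select("replicate", "exit_id", "time_s", "cumulative_exited")
  }))
}

#' Write a report bundle for one or more ensembles
#'
#' Writes aggregate CSVs (MI, force, leaving profiles), overlay figures of
#' MI and force against time, the MI-versus-force scatter with fitted line
#' and correlation annotation, and a JSON manifest (scenario hashes, seeds,
#' package version). An annotation marks the conventional 1500 N
#' fatality-risk force level on force plots; no injury outcome is modelled.
#'
#' @param ensembles Named list of `crush_ensemble` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(ensembles, dir) {
  stopifnot(length(ensembles) >= 1)
  if (is.null(names(ensembles))) {
    names(ensembles) <- vapply(ensembles, `[[`, "", "label")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "crushmi",
                   version = as.character(utils::packageVersion("crushmi")),
                   ensembles = list())
  for (nm in names(ensembles)) {
    en <- ensembles[[nm]]
    readr::write_csv(en$mi_aggregate, file.path(dir, paste0(nm, "_mi.csv")))
    readr::write_csv(en$force_aggregate, file.path(dir, paste0(nm, "_force.csv")))
    lv <- leaving_profiles(en)
    if (!is.null(lv) && nrow(lv)) {
      readr::write_csv(lv, file.path(dir, paste0(nm, "_leaving.csv")))
    }
    pairs <- mi_force_pairs(en)
    readr::write_csv(pairs, file.path(dir, paste0(nm, "_mi_force_pairs.csv")))
    manifest$ensembles[[nm]] <- list(label = en$label, seeds = en$seeds,
                                     spec_hash = en$spec_hash,
                                     n_replicates = nrow(en$replicates))
  }
  p <- plot_series(ensembles)
  ggplot2::ggsave(file.path(dir, "series.png"), p, width = 8, height = 5,
                  dpi = 150)
  for (nm in names(ensembles)) {
    cr <- tryCatch(correlate_mi_force(ensembles[[nm]]), error = function(e) NULL)
    if (!is.null(cr)) {
      ps <- plot_mi_force_scatter(ensembles[[nm]], cr)
      ggplot2::ggsave(file.path(dir, paste0(nm, "_scatter.png")), ps,
                      width = 6, height = 5, dpi = 150)
      manifest$ensembles[[nm]]$pearson_r <- cr$r
      manifest$ensembles[[nm]]$p_two_tailed <- cr$p_two_tailed
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
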