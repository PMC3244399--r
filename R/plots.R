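#' Overlay MI and force series of one or more ensembles
#'
#' Reproduces the standard diagnostic view: the mutual-information order
#' parameter and the population-averaged contact force against time, one
#' facet per quantity, coloured by scenario. The conventional 1500 N
#' fatality-risk level is marked on the force facet.
#'
#' @param ensembles A `crush_ensemble` or named list of them.
#' @return A ggplot object.
#' @export
plot_series <- function(ensembles) {
  if (inherits(ensembles, "crush_ensemble")) {
    ensembles <- stats::setNames(list(ensembles), ensembles$label)
  }
  long <- dplyr::bind_rows(lapply(names(ensembles), function(nm) {
    en <- ensembles[[nm]]
    dplyr::bind_rows(
      tibble::tibble(scenario = nm, time_s = en$mi_aggregate$time_s,
                     value = en$mi_aggregate$mi_mean_bits,
                     se = en$mi_aggregate$mi_se_bits,
                     quantity = "Mutual information (bits)"),
      tibble::tibble(scenario = nm, time_s = en$force_aggregate$time_s,
                     value = en$force_aggregate$mean_force_N,
                     se = en$force_aggregate$force_se_N,
                     quantity = "Mean contact force (N)"))
  }))
  long$se <- dplyr::coalesce(long$se, 0)  # single replicate: no band
  ref <- tibble::tibble(quantity = "Mean contact force (N)", y = 1500)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$se,
                                      ymax = .data$value + .data$se,
                                      fill = .data$scenario),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of force against MI with fitted line
#'
#' @param ensemble A `crush_ensemble`.
#' @param correlation Optional `crush_correlation` to annotate.
#' @return A ggplot object.
#' @export
plot_mi_force_scatter <- function(ensemble, correlation = NULL) {
  pairs <- mi_force_pairs(ensemble)
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mi_mean_bits,
                                           y = .data$mean_force_N)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "Mutual information (bits)",
                  y = "Mean contact force (N)",
                  title = ensemble$label) +
    ggplot2::theme_minimal()
  if (!is.null(correlation)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("Pearson r = %.3f, two-tailed p = %.2g, n = %d",
                         correlation$r, correlation$p_two_tailed,
                         correlation$n_points))
  }
  p
}

#' @rdname plot_series
#' @param object A `crush_ensemble`.
#' @param ... Unused.
#' @export
autoplot.crush_ensemble <- function(object, ...) plot_series(object)

#' Plot a single simulation run
#'
#' @param object A `crush_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crush_sim <- function(object, ...) {
  long <- dplyr::bind_rows(
    if (!is.null(object$mi))
      tibble::tibble(time_s = object$mi$time_s,
                     value = object$mi$mi_mean_bits,
                     quantity = "Mutual information (bits)"),
    tibble::tibble(time_s = object$force$time_s,
                   value = object$force$mean_force_N,
                   quantity = "Mean contact force (N)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = object$scenario_label) +
    ggplot2::theme_minimal()
}
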