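#' Plot a population rate histogram
#'
#' @param object A `cpg_histogram` from [population_histogram()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cpg_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid / 1000, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "rate (spikes/(N·s))",
                  title = paste0(object$population[1], " (", object$side[1], ")")) +
    ggplot2::theme_minimal()
}

#' Plot a frequency-versus-excitation sweep
#'
#' Mean flexor burst frequency against the drug-excitation parameter, per
#' topology, with replicate points.
#'
#' @param object A `cpg_sweep` from [alpha_sweep()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cpg_sweep <- function(object, ...) {
  means <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$alpha, .data$topology),
    frequency_hz = mean(.data$frequency_hz), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$alpha, y = .data$frequency_hz,
                               colour = .data$topology)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble::as_tibble(object), alpha = 0.5) +
    ggplot2::labs(x = expression(alpha), y = "burst frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Spike raster plot
#'
#' @param recordings A `cpg_recordings`.
#' @param populations Populations to show (default all).
#' @param sides Sides to show (default all).
#' @return A ggplot.
#' @export
plot_raster <- function(recordings, populations = NULL, sides = NULL) {
  sp <- recordings$spikes
  if (!is.null(populations)) sp <- sp[sp$population %in% populations, ]
  if (!is.null(sides)) sp <- sp[sp$side %in% sides, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time_ms / 1000, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.5) +
    ggplot2::facet_grid(ggplot2::vars(.data$population, .data$side),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}
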