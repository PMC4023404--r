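#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_hline geom_vline facet_wrap labs scale_x_log10 scale_y_log10 theme_bw
NULL

#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' One panel per state component over time.
#'
#' @param object an `erk_trajectory`.
#' @param states which state components to show.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot erk_trajectory
#' @export
autoplot.erk_trajectory <- function(object,
                                    states = c("M2", "E2c", "EBc", "E2n",
                                               "EBn", "Pn"), ...) {
  long <- tidyr::pivot_longer(as_tibble(as.data.frame(object)),
                              dplyr::all_of(states),
                              names_to = "state", values_to = "amount")
  ggplot(long, aes(x = .data$time_min, y = .data$amount)) +
    geom_line() +
    facet_wrap(~state, scales = "free_y") +
    labs(x = "time (min)", y = "amount (fraction of total ERK)") +
    theme_bw()
}

#' Plot model readouts
#'
#' Readout traces from [erk_observe()], one panel per readout, optionally
#' overlaid on a dataset.
#'
#' @param readouts tibble from [erk_observe()].
#' @param dataset optional `erk_dataset` to overlay as points.
#' @return A ggplot object.
#' @export
plot_readouts <- function(readouts, dataset = NULL) {
  gg <- ggplot(readouts, aes(x = .data$time_min, y = .data$value)) +
    geom_line(color = "firebrick") +
    facet_wrap(~readout, scales = "free_y") +
    labs(x = "time (min)", y = "readout value") +
    theme_bw()
  if (!is.null(dataset)) {
    gg <- gg + geom_point(data = as_tibble(as.data.frame(dataset)),
                          alpha = 0.4, size = 0.8)
  }
  gg
}

#' Plot an ensemble as a buffering-strength scatter
#'
#' Cytosolic vs nuclear substrate buffering strength for every accepted
#' parameter set, colored by buffering mode, on log axes with the mode
#' boundary marked.
#'
#' @param object an `erk_ensemble`.
#' @param boundary mode boundary passed to [classify_modes()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot erk_ensemble
#' @export
autoplot.erk_ensemble <- function(object, boundary = 1, ...) {
  cm <- classify_modes(object, boundary = boundary)
  floor_b <- function(x) pmax(x, 1e-4)
  ggplot(cm, aes(x = floor_b(.data$B_c), y = floor_b(.data$B_n),
                 color = .data$mode)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_hline(yintercept = boundary, linetype = 2) +
    geom_vline(xintercept = boundary, linetype = 2) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "cytosolic buffering strength B_c",
         y = "nuclear buffering strength B_n") +
    theme_bw()
}

#' Plot ensemble prediction envelopes
#'
#' Mean +/- s.d. ribbons of each readout under each protocol.
#'
#' @param object an `erk_predictions` from [run_predictions()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot erk_predictions
#' @export
autoplot.erk_predictions <- function(object, ...) {
  ggplot(object$traces, aes(x = .data$time_min, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                fill = "steelblue", alpha = 0.3) +
    geom_line(color = "steelblue4") +
    ggplot2::facet_grid(readout ~ protocol, scales = "free_y") +
    labs(x = "time (min)", y = "readout (normalized)") +
    theme_bw()
}

#' Plot a species breakdown
#'
#' Stacked-area view of the eight ERK pools over time.
#'
#' @param breakdown tibble from [species_breakdown()].
#' @return A ggplot object.
#' @export
plot_species_breakdown <- function(breakdown) {
  breakdown$species <- factor(breakdown$species,
                              levels = c("c", "cp", "cpp", "cs",
                                         "n", "np", "npp", "ns"))
  ggplot(breakdown, aes(x = .data$time_min, y = .data$fraction,
                        fill = .data$species)) +
    ggplot2::geom_area() +
    labs(x = "time (min)", y = "fraction of total ERK") +
    theme_bw()
}
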