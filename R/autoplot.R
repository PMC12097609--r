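# ggplot2 convenience plots. Plots are a convenience surface, never a
# tested numerical contract.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Population time series, one facet per compartment (log scale optional),
#' with the strategy level overlaid as its own facet when dynamic.
#'
#' @param object An `ecoepi_traj`.
#' @param compartments Which series to show.
#' @param log10 Log-scale the population axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecoepi_traj <- function(object, compartments = c("S", "I", "P", "x"),
                                 log10 = FALSE, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(compartments),
                              names_to = "compartment", values_to = "density")
  long$compartment <- factor(long$compartment, levels = compartments)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~compartment, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time", y = "density / level")
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a scan
#'
#' For a one-parameter scan: the classic bifurcation diagram (one dot per
#' post-transient peak value, per compartment facet), coloured by regime.
#' For a two-parameter scan: a regime tile map.
#'
#' @param object An `ecoepi_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecoepi_scan <- function(object, ...) {
  swept <- attr(object, "swept")
  if (length(swept) == 1) {
    long <- tidy(object)
    ggplot2::ggplot(long, ggplot2::aes(x = .data[[swept]], y = .data$peak,
                                       colour = .data$regime)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::facet_wrap(~compartment, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = swept, y = "post-transient peak value")
  } else {
    ggplot2::ggplot(tibble::as_tibble(object),
                    ggplot2::aes(x = .data[[swept[1]]], y = .data[[swept[2]]],
                                 fill = .data$regime)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = swept[1], y = swept[2])
  }
}
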