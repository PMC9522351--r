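#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spike raster
#'
#' @param object A `spike_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spike_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_ms, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Plot an epigenesis trajectory
#'
#' `type = "percentiles"` draws the weight percentiles over presentations
#' (median highlighted); `type = "states"` draws the eliminated /
#' undetermined / selected fractions.
#'
#' @param object An `epigenesis_trajectory` or `local_network`.
#' @param type `"percentiles"` or `"states"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.epigenesis_trajectory <- function(object,
                                           type = c("percentiles", "states"),
                                           ...) {
  type <- match.arg(type)
  if (type == "percentiles") {
    pt <- percentile_trajectories(object)
    ggplot2::ggplot(pt, ggplot2::aes(x = .data$presentations,
                                     y = .data$weight,
                                     group = .data$percentile)) +
      ggplot2::geom_line(color = "grey30", linewidth = 0.3) +
      ggplot2::geom_line(data = dplyr::filter(pt, .data$percentile == 50),
                         color = "steelblue", linewidth = 1) +
      ggplot2::labs(x = "presentations", y = "synaptic weight") +
      ggplot2::theme_minimal()
  } else {
    sf <- state_fractions(object) |>
      tidyr::pivot_longer(c("eliminated", "undetermined", "selected"),
                          names_to = "state", values_to = "fraction")
    ggplot2::ggplot(sf, ggplot2::aes(x = .data$presentations,
                                     y = .data$fraction,
                                     color = .data$state)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::scale_color_manual(values = c(eliminated = "firebrick",
                                             undetermined = "grey50",
                                             selected = "forestgreen")) +
      ggplot2::labs(x = "presentations", y = "fraction of synapses") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.local_network <- function(object, ...) {
  autoplot.epigenesis_trajectory(object$trajectory, ...)
}

#' Plot the HSV receptive-field reconstruction of the S2 cells
#'
#' Hue encodes the dominant orientation, saturation the connection strength
#' (value fixed at 100%), one facet per S2 cell.
#'
#' @param net A `local_network`.
#' @return A ggplot.
#' @export
plot_reconstruction <- function(net) {
  rec <- hsv_reconstruction(net)
  rec$fill <- grDevices::hsv(rec$hue / (2 * pi),
                             pmin(rec$saturation / max(rec$saturation, 1e-12), 1),
                             1)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$col, y = -.data$row,
                                    fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot a sweep accuracy heatmap
#'
#' Mean held-out accuracy per (spontaneous rate, excitatory fraction) cell.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$rate_hz),
                               y = factor(.data$excitatory_fraction),
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$accuracy)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "spontaneous rate (Hz)", y = "excitatory fraction",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot the learning curve of a conditioning run
#'
#' Sliding-window accuracy over trials.
#'
#' @param object A `conditioning_run`.
#' @param window Sliding-window length.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conditioning_run <- function(object, window = 20L, ...) {
  cs <- cumsum(object$trials$correct)
  n <- length(cs)
  if (n < window) window <- n
  acc <- (cs[window:n] - c(0, cs[seq_len(n - window)])) / window
  df <- tibble::tibble(trial = window:n, accuracy = acc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$accuracy)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "trial",
                  y = sprintf("accuracy (window = %d)", window)) +
    ggplot2::theme_minimal()
}
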