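#' Plot the establishment of plasticity for one simulation
#'
#' Total change in macroscopic synaptic strength versus pairing count, with
#' the neutral band shaded.
#'
#' @param object An `stdp_sim` object.
#' @param included Pathways entering the readout product (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stdp_sim <- function(object, included = NULL, ...) {
  tc <- total_change(object, included = included)
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$pairing, y = .data$total_change)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 1 - plasticity_bands$neutral,
                      ymax = 1 + plasticity_bands$neutral,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey30") +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pairing count",
                  y = "total change in synaptic strength",
                  title = sprintf("%s engine", object$engine)) +
    ggplot2::theme_minimal()
}

#' Plot a plasticity sweep
#'
#' Heatmaps use a log colour scale centred on 1 (no change), matching the
#' usual presentation of timing/pairing-number plasticity maps.
#'
#' @param object An `stdp_sweep` tibble (from [stdp_heatmap()],
#'   [frequency_sweep()] or [triplet_map()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stdp_sweep <- function(object, ...) {
  meta <- attr(object, "meta")
  fill_scale <- ggplot2::scale_fill_gradient2(
    low = "#2166ac", mid = "white", high = "#b2182b",
    midpoint = 0, name = "log2 change")
  if (identical(meta$kind, "frequency_sweep")) {
    return(
      ggplot2::ggplot(object,
                      ggplot2::aes(x = 1000 * .data$dt_folded,
                                   y = .data$mean_change,
                                   colour = factor(.data$freq))) +
        ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey30") +
        ggplot2::geom_pointrange(ggplot2::aes(
          ymin = .data$mean_change - .data$sd_change,
          ymax = .data$mean_change + .data$sd_change)) +
        ggplot2::labs(x = "folded spike timing (ms)", y = "total change",
                      colour = "frequency (Hz)") +
        ggplot2::theme_minimal())
  }
  if (identical(meta$kind, "triplet_map")) {
    return(
      ggplot2::ggplot(object,
                      ggplot2::aes(x = 1000 * .data$dt1, y = 1000 * .data$dt2,
                                   fill = log2(.data$total_change))) +
        ggplot2::geom_tile() + fill_scale +
        ggplot2::facet_wrap(~pairing) +
        ggplot2::labs(x = expression(Delta * t[1] ~ "(ms)"),
                      y = expression(Delta * t[2] ~ "(ms)")) +
        ggplot2::theme_minimal())
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pairing, y = 1000 * .data$dt,
                               fill = log2(.data$total_change))) +
    ggplot2::geom_tile() + fill_scale +
    ggplot2::labs(x = "pairing count", y = "spike timing (ms)") +
    ggplot2::theme_minimal()
}

#' Plot a calcium trace with pathway thresholds
#'
#' @param trace A [calcium_trace()].
#' @param model Optional [synapse_model()] whose base thresholds to draw.
#' @param from,to Time window, seconds (defaults to the trace extent plus
#'   ten decay constants).
#' @param n Grid resolution.
#' @return A ggplot object.
#' @export
plot_calcium_trace <- function(trace, model = NULL, from = NULL, to = NULL,
                               n = 2000) {
  from <- from %||% (min(trace$events$time) - trace$tau_ca)
  to <- to %||% (max(trace$events$time) + 10 * trace$tau_ca)
  tt <- seq(from, to, length.out = n)
  df <- tibble::tibble(t = tt, c = ca_value(trace, tt))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$c)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "calcium concentration") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    th <- purrr::map_dfr(model$pathways, function(pw)
      tibble::tibble(pathway = pw$name,
                     threshold = c(pw$theta0_p, pw$theta0_d),
                     mechanism = c("LTP", "LTD")))
    th <- dplyr::filter(th, is.finite(.data$threshold))
    p <- p + ggplot2::geom_hline(
      data = th,
      ggplot2::aes(yintercept = .data$threshold, colour = .data$pathway,
                   linetype = .data$mechanism))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
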