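#' Survival-curve plot
#'
#' Step plot of the Kaplan-Meier estimate with its 95% confidence band
#' (dashed) and censor marks, the standard presentation of residence-lifetime
#' survival data.
#'
#' @param object A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- object$curve
  d0 <- dplyr::bind_rows(tibble::tibble(time = 0, surv = 1, lower = 1, upper = 1,
                                        n_risk = object$n, n_event = 0L,
                                        n_censor = 0L), d)
  cens <- d[d$n_censor > 0, ]
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dashed",
                       na.rm = TRUE) +
    ggplot2::geom_point(data = cens, shape = 3, na.rm = TRUE) +
    ggplot2::labs(x = "Residence time (s)", y = "Survival probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Event-raster plot of residence pulses
#'
#' One row per DNA spot; each pulse drawn as a horizontal segment over the
#' acquisition, colored by channel — the standard per-template residence
#' overview of a CoSMoS time-lapse.
#'
#' @param pulses Pulse tibble from [derive_pulses()].
#' @param total_s Acquisition length (s) for the x-axis limit.
#' @return A ggplot object.
#' @export
plot_pulse_raster <- function(pulses, total_s = NULL) {
  p <- ggplot2::ggplot(pulses) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$onset_s, xend = .data$end_s,
                                       y = .data$spot, yend = .data$spot,
                                       color = .data$channel),
                          linewidth = 1.2) +
    ggplot2::labs(x = "Time (s)", y = "DNA spot") +
    ggplot2::theme_classic()
  if (!is.null(total_s)) p <- p + ggplot2::xlim(0, total_s)
  p
}

#' z-trace plot with binarization threshold
#'
#' @param traces Trace tibble from [extract_traces()].
#' @param spot_id Spot to plot.
#' @param threshold z threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_trace <- function(traces, spot_id, threshold = 3) {
  d <- traces[traces$spot == spot_id, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), ncol = 1) +
    ggplot2::labs(x = "Time (s)", y = "z-normalized intensity") +
    ggplot2::theme_classic()
}
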