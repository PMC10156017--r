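#' ggplot2 autoplot methods for result objects
#'
#' Quick-look figures: stimulus waveforms, PSTH heat/line plots, response
#' decompositions, F-I curves, limit cycles and fit diagnostics.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_tile labs facet_wrap theme_minimal scale_fill_viridis_c
NULL

#' @export
autoplot.conc_waveform <- function(object, ...) {
  ggplot(object, aes(.data$time_s, .data$ppm)) +
    geom_line() +
    labs(x = "time (s)", y = "concentration (ppm)") +
    theme_minimal()
}

#' @export
autoplot.al_psth <- function(object, ...) {
  if (length(unique(object$channel)) == 1) {
    ggplot(object, aes(.data$time_s, .data$rate_hz)) +
      geom_line() +
      labs(x = "time (s)", y = "rate (Hz)") +
      theme_minimal()
  } else {
    ggplot(object, aes(.data$time_s, factor(.data$channel),
                       fill = .data$rate_hz)) +
      geom_tile() +
      scale_fill_viridis_c(name = "rate (Hz)") +
      labs(x = "time (s)", y = "channel") +
      theme_minimal()
  }
}

#' @export
autoplot.al_decomposition <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", "signal", "steady", "transient")],
    -"time_s", names_to = "component", values_to = "value")
  ggplot(long, aes(.data$time_s, .data$value)) +
    geom_line() +
    geom_vline(xintercept = attr(object, "jump_times"), linetype = 3) +
    facet_wrap(~component, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' @export
autoplot.fi_curve <- function(object, ...) {
  ggplot(object, aes(.data$current_uA, .data$rate_hz)) +
    geom_line() + geom_point(size = 0.4) +
    labs(x = "injected current (uA)", y = "firing rate (Hz)") +
    theme_minimal()
}

#' @export
autoplot.phase_trajectory <- function(object, ...) {
  ggplot(object, aes(.data$v_mV, .data$n)) +
    geom_line() +
    labs(x = "V (mV)", y = "n (K activation)") +
    theme_minimal()
}

#' @export
autoplot.al_fit <- function(object, ...) {
  sc <- object$screen
  ggplot(sc, aes(.data$sample, .data$objective, colour = .data$feasible)) +
    geom_point(alpha = 0.5) +
    labs(x = "screening sample", y = "angular distance",
         title = paste("pathway:", object$pathway)) +
    theme_minimal()
}

#' Architecture-comparison summary plot
#' @param comparison output of [run_architecture_comparison()]
#' @export
plot_architecture_comparison <- function(comparison) {
  ggplot(comparison, aes(.data$variant, .data$objective)) +
    ggplot2::geom_violin() +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.3) +
    labs(x = NULL, y = "identity-recovery objective (angular distance)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
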