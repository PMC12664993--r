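#' Raincloud-style plot of a gating metric series
#'
#' Half-violin density, jittered per-frame points and median/extrema bars,
#' one panel per metric, grouped by replicate.
#'
#' @param object a `metric_series` from [gating_series()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metric_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$replicate, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, width = 0.9) +
    ggplot2::geom_jitter(width = 0.12, size = 0.4, alpha = 0.35) +
    ggplot2::stat_summary(fun = stats::median, fun.min = min, fun.max = max,
                          geom = "pointrange", linewidth = 0.4, size = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' Plot a pore radius profile
#'
#' Radius against axial position; prime-position annotations (if present)
#' are drawn as labelled vertical lines.
#'
#' @param object a `pore_profile` from [pore_radius_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pore_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z along pore axis (Å)", y = "pore radius (Å)") +
    ggplot2::theme_minimal()
  primes <- attr(object, "primes")
  if (!is.null(primes) && nrow(primes)) {
    ok <- primes[!is.na(primes$z), ]
    p <- p +
      ggplot2::geom_vline(data = ok, ggplot2::aes(xintercept = .data$z),
                          linetype = "dashed", colour = "grey50") +
      ggplot2::geom_text(data = ok,
                         ggplot2::aes(x = .data$z, y = Inf, label = .data$label),
                         vjust = 1.2, size = 3)
  }
  p
}

#' Plot mean pore profiles with SEM ribbon
#'
#' @param stats output of [profile_stats()].
#' @return a ggplot.
#' @export
plot_profile_stats <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$z, y = .data$radius_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$radius_mean - .data$radius_sem,
                                      ymax = .data$radius_mean + .data$radius_sem),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z along pore axis (Å)",
                  y = "mean pore radius (Å)") +
    ggplot2::theme_minimal()
}

#' Lobe-position map: z against distance from the pore axis
#'
#' Mirrors the standard lobe-COM scatter: every frame of every trace as a
#' point, starting positions as black beads.
#'
#' @param object a `lobe_trace` tibble (one or many traces).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lobe_trace <- function(object, ...) {
  starts <- object |> filter(.data$frame == 1L)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radial, y = .data$z,
                                       colour = .data$chain)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_point(data = starts, colour = "black", size = 1.8) +
    ggplot2::facet_wrap(~lobe) +
    ggplot2::labs(x = "distance from pore axis (Å)",
                  y = "z along pore axis (Å)") +
    ggplot2::theme_minimal()
}

#' Plot ion displacement series with the residence threshold
#'
#' @param object a `residence_series` from [ion_residence()].
#' @param threshold threshold line (Angstrom).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.residence_series <- function(object, threshold = 5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns,
                                       y = .data$displacement,
                                       colour = .data$ion_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "time (ns)", y = "displacement from initial pose (Å)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
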