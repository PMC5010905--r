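#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a topology trace
#'
#' Distance to the focal tree against generation, one colour per chain. A
#' healthy chain shows a stationary band with rapid fluctuation; slow
#' excursions indicate autocorrelation, and two alternating bands indicate
#' switching between posterior modes.
#'
#' @param object A [topology_trace()] (possibly several chains bound
#'   together with shared focal tree).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topology_trace
#' @export
autoplot.topology_trace <- function(object, ...) {
  metric <- attr(object, "metric")
  dat <- trace_plot_data(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generation, y = .data$distance,
                                    colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "generation",
                  y = paste0("distance to focal tree (", metric$name, ")"),
                  title = "Topology trace") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.topology_trace
#' @param trace A [topology_trace()].
#' @export
plot_topology_trace <- function(trace, ...) autoplot.topology_trace(trace, ...)

#' Plot a jump distance profile
#'
#' Mean topological distance between pairs of trees against the sampling
#' interval separating them. Flat means uncorrelated samples; a rising curve
#' that saturates estimates the autocorrelation time at the saturation lag;
#' a curve still rising at the largest lag only bounds it from below.
#'
#' @param object A [jump_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jump_profile
#' @export
autoplot.jump_profile <- function(object, ...) {
  metric <- attr(object, "metric")
  dat <- jump_plot_data(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$interval, y = .data$mean_distance)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_line(colour = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "sampling interval",
                  y = paste0("mean distance (", metric$name, ")"),
                  title = "Jump distance plot") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.jump_profile
#' @param profile A [jump_profile()].
#' @export
plot_jump_profile <- function(profile, ...) autoplot.jump_profile(profile, ...)
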