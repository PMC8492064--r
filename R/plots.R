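#' Plot a simulation snapshot
#'
#' Cells at a chosen time, coloured by fate, with the anterior wall at the
#' top (y increases posteriorly, so the axis is reversed for an
#' embryo-like orientation).
#'
#' @param object A `sim_result`.
#' @param time_h Snapshot time; defaults to the last.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_result <- function(object, time_h = NULL, ...) {
  if (is.null(time_h)) time_h <- max(object$snapshots$time_h)
  s <- snapshot_at(object, time_h)
  ggplot2::ggplot(s, ggplot2::aes(.data$x_unit, .data$y_unit,
                                  colour = .data$state)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(progenitor = "#E6AB02",
                                            NT = "#1B9E77", PSM = "#D95F02")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (model units)", y = "y (model units, posterior down)",
                  colour = "fate",
                  title = sprintf("t = %.1f h (%s regime)", unique(s$time_h),
                                  object$config$regime))
}

#' Plot per-fate counts over time
#'
#' @param result A `sim_result`.
#' @return A ggplot.
#' @export
plot_counts <- function(result) {
  ggplot2::ggplot(count_timeseries(result),
                  ggplot2::aes(.data$time_h, .data$n, colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "cells", colour = "fate")
}

#' Plot an MSD curve
#'
#' @param object An `msd_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_h, .data$msd_um2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag (h)", y = expression(MSD ~ (mu * m^2)))
}

#' Rose plot of a velocity-weighted angle distribution
#'
#' @param angles Output of [angle_distribution()].
#' @return A ggplot in polar coordinates, 0 degrees = posterior.
#' @export
plot_angle_distribution <- function(angles) {
  ggplot2::ggplot(angles, ggplot2::aes(.data$angle_mid_deg, .data$weight)) +
    ggplot2::geom_col(width = 360 / nrow(angles), fill = "grey40") +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = c(-90, 0, 90, 180)) +
    ggplot2::labs(x = "angle (deg, 0 = posterior)", y = "weight")
}

#' Plot a path profile
#'
#' Mean Sox2 and Bra per volume along the posterior-to-anterior path.
#'
#' @param object A `path_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.path_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("sox2_mean", "bra_mean"),
                              names_to = "channel", values_to = "mean")
  ggplot2::ggplot(long, ggplot2::aes(.data$volume, .data$mean,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$volume) +
    ggplot2::labs(x = "volume (posterior to anterior)",
                  y = "mean normalized intensity", colour = NULL)
}
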