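# ggplot2 visualisations for trajectories, datasets and GA fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Faceted line plot of the nine states (or a chosen subset) over
#' time, with vaccination days marked.
#'
#' @param object A `ctl_trajectory`.
#' @param states Character vector of state columns to show (default
#'   all nine).
#' @param log10 Show the value axis on a log10 scale (zeros dropped by
#'   the scale; default `TRUE` since the states span many decades).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctl_trajectory <- function(object, states = .STATE_NAMES,
                                    log10 = TRUE, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  "time", dplyr::all_of(states)),
    -"time", names_to = "state", values_to = "value")
  long$state <- factor(long$state, levels = .STATE_NAMES)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL)
  sched <- attr(object, "schedule")
  if (!is.null(sched) && nrow(sched)) {
    gg <- gg + ggplot2::geom_vline(xintercept = sched$day,
                                   linetype = "dotted", colour = "grey50")
  }
  if (log10) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' @export
plot.ctl_trajectory <- function(x, ...) print(autoplot(x, ...))

#' Plot a calibration dataset against model predictions
#'
#' @param data An experimental dataset tibble (see
#'   [as_experimental_dataset()]).
#' @param p Optional `model_parameters`; when given, the model curves
#'   under the dataset's calibration protocol are overlaid.
#' @param schedule Vaccination protocol for the overlay (default
#'   single dose 1.1e6 on day 5).
#' @param dt Integration step for the overlay curve.
#' @return A ggplot object (points with SEM error bars, faceted by
#'   observable; solid model lines if `p` is given).
#' @export
plot_dataset <- function(data, p = NULL,
                         schedule = vaccination_schedule(5, 1.1e6),
                         dt = 0.05) {
  data <- as_experimental_dataset(data)
  gg <- ggplot2::ggplot(data, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sem,
                                        ymax = .data$value + .data$sem),
                           width = 0.5, na.rm = TRUE) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL)
  if (!is.null(p)) {
    traj <- simulate_trajectory(p, schedule = schedule,
                                t1 = max(data$day) + 1, dt = dt)
    curves <- observe(traj, p)
    curves$day <- traj$time
    long <- tidyr::pivot_longer(curves, -"day", names_to = "observable",
                                values_to = "value")
    gg <- gg + ggplot2::geom_line(data = long, colour = "steelblue")
  }
  gg
}

#' Plot GA fitness history
#'
#' @param object A `ga_fit`.
#' @param ... Unused.
#' @return A ggplot of per-generation best and mean fitness (log10
#'   scale) with the monotone best-so-far envelope.
#' @export
autoplot.ga_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"generation",
                              names_to = "series", values_to = "fitness")
  long <- long[is.finite(long$fitness), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "fitness")
}

#' @export
plot.ga_fit <- function(x, ...) print(autoplot(x, ...))
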