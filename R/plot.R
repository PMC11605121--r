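# ggplot2 visualisations: stick diagrams over the distance axis, sweep
# outcome maps, and margin-of-stability step series.

#' Stick diagram of a walking trial
#'
#' Draws the segment line-work of the walker at regularly sampled instants
#' over the travelled distance, the standard way of displaying these
#' simulations.  A fallen trial is drawn through the fall frame and stops.
#'
#' @param traj trajectory tibble from [simulate_walk()].
#' @param interval sampling interval between poses, s.
#' @param anthro the anthropometry used for the run.
#' @return a ggplot object.
#' @export
plot_stick_diagram <- function(traj, interval = 0.5,
                               anthro = build_anthropometry()) {
  stopifnot(interval > 0)
  if (nrow(traj) == 0) abort("empty trajectory")
  times <- seq(min(traj$t), max(traj$t), by = interval)
  idx <- vapply(times, function(tt) which.min(abs(traj$t - tt)), 1L)
  segs <- stick_segments(traj[idx, , drop = FALSE], anthro)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       group = .data$pose),
                          linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "distance (m)", y = "height (m)") +
    ggplot2::theme_minimal()
}

# endpoints of each segment at the sampled poses
stick_segments <- function(tr, anthro) {
  ends <- list(
    hat = list(c(0, (1 - 0.45) * anthro$segments$length[1]),
               c(0, -0.45 * anthro$segments$length[1])),
    pelvis = list(c(0, 0.5 * anthro$segments$length[2]),
                  c(0, -0.5 * anthro$segments$length[2])),
    thigh_r = list(c(0, 0.433 * anthro$segments$length[3]),
                   c(0, -(1 - 0.433) * anthro$segments$length[3])),
    thigh_l = list(c(0, 0.433 * anthro$segments$length[4]),
                   c(0, -(1 - 0.433) * anthro$segments$length[4])),
    shank_r = list(c(0, 0.433 * anthro$segments$length[5]),
                   c(0, -(1 - 0.433) * anthro$segments$length[5])),
    shank_l = list(c(0, 0.433 * anthro$segments$length[6]),
                   c(0, -(1 - 0.433) * anthro$segments$length[6])),
    foot_r = list(anthro$foot$heel, anthro$foot$toe),
    foot_l = list(anthro$foot$heel, anthro$foot$toe)
  )
  purrr::map_dfr(names(ends), function(seg) {
    p0 <- point_world(tr, seg, ends[[seg]][[1]])
    p1 <- point_world(tr, seg, ends[[seg]][[2]])
    tibble(pose = seq_len(nrow(tr)), segment = seg,
           x0 = p0$x, y0 = p0$y, x1 = p1$x, y1 = p1$y)
  })
}

#' @export
autoplot.sg_sweep <- function(object, ...) {
  dat <- mutate(object,
                fall = as.integer(.data$outcome != "no_fall"),
                kind = dplyr::case_when(
                  .data$outcome == "slip_fall" ~ "slip-induced",
                  .data$outcome == "trip_fall" ~ "trip-induced",
                  TRUE ~ "no fall"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mu_s, y = .data$fall,
                                    colour = .data$kind,
                                    shape = .data$kind)) +
    ggplot2::geom_jitter(width = 0.008, height = 0.03, size = 2) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("no fall (0)", "fall (1)")) +
    ggplot2::scale_colour_manual(values = c("no fall" = "black",
                                            "slip-induced" = "blue",
                                            "trip-induced" = "red")) +
    ggplot2::scale_shape_manual(values = c("no fall" = 16,
                                           "slip-induced" = 4,
                                           "trip-induced" = 4)) +
    ggplot2::labs(x = expression(mu[s]), y = NULL,
                  title = unique(dat$model)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sg_mos <- function(object, ...) {
  minima <- mos_step_minima(object)
  long <- tidyr::pivot_longer(minima, -"step", names_to = "direction",
                              values_to = "mos")
  long$direction <- sub("min_mos_", "", long$direction)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$mos,
                                     colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "minimum MOS (m)") +
    ggplot2::theme_minimal()
}

#' Plot per-step minimum margins of stability
#'
#' @param mos an [compute_mos()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_mos_minima <- function(mos, ...) autoplot.sg_mos(mos, ...)
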