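#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_segment geom_tile
#'   geom_col geom_contour facet_wrap labs scale_fill_gradient2 theme_minimal
#'   coord_polar geom_hline geom_errorbar
NULL

#' Plot an averaged response cycle
#'
#' Mean eye response and stimulus over one cycle, the standard single-cycle
#' summary of a VOR/OKR recording.
#'
#' @param object a `cycle_average`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cycle_average <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"phase",
                            names_to = "channel", values_to = "angle")
  ggplot(df, aes(x = .data$phase, y = .data$angle,
                 colour = .data$channel)) +
    geom_line(linewidth = 0.8) +
    labs(x = "cycle phase", y = "angle (deg)",
         title = sprintf("averaged cycle (n = %d)",
                         attr(object, "n_cycles_used"))) +
    theme_minimal()
}

#' Plot a kinematics series
#'
#' Swim speed, tail deflection velocity and cumulative distance against
#' time.
#'
#' @param object a `kinematics_series`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.kinematics_series <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("time", "swim_speed", "tail_velocity",
                        "cumulative_distance")],
    -"time", names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~metric, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Swim-event map
#'
#' Active-locomotion periods as black bars, one row per recording.
#'
#' @param bout_list a named list of bout tibbles (from [detect_bouts()]).
#' @return A ggplot.
#' @export
plot_bout_map <- function(bout_list) {
  if (inherits(bout_list, "data.frame")) bout_list <- list(recording = bout_list)
  df <- purrr::imap_dfr(bout_list, ~ mutate(.x, recording = .y))
  ggplot(df, aes(x = .data$start, xend = .data$end,
                 y = .data$recording, yend = .data$recording)) +
    geom_segment(linewidth = 4, colour = "black") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot a cross-section area profile
#'
#' Lumen cross-section area against normalized duct arclength, with the
#' profile mean marked; a pre-ampullary stenosis appears as a sharp dip.
#'
#' @param object a `cs_profile`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cs_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$s, y = .data$area)) +
    geom_line() +
    geom_hline(yintercept = attr(object, "cs_mean"), linetype = 2) +
    labs(x = "normalized arclength", y = expression(area ~ (mu * m^2))) +
    theme_minimal()
}

#' Plot spino-ocular gain versus tail amplitude
#'
#' @param object a `gain_amplitude` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gain_amplitude <- function(object, ...) {
  b <- object$binned
  ggplot(b, aes(x = .data$amplitude, y = .data$gain)) +
    geom_errorbar(aes(ymin = .data$gain - .data$gain_sd,
                      ymax = .data$gain + .data$gain_sd), width = 0) +
    geom_point() +
    geom_line(data = tibble(amplitude = b$amplitude,
                            gain = predict(object$fit, b)),
              linetype = 2) +
    labs(x = "tail amplitude (deg, peak-to-peak)", y = "spino-ocular gain") +
    theme_minimal()
}

#' Polar phase plot
#'
#' Individual response phases on the circle with the mean vector, the
#' classic polar summary of phase clustering.
#'
#' @param phases angles in degrees (negative = lead).
#' @return A ggplot.
#' @export
plot_phase_polar <- function(phases) {
  cs <- circular_summary(phases)
  df <- tibble(phase = (phases + 360) %% 360)
  ggplot(df, aes(x = .data$phase, y = 1)) +
    geom_point(alpha = 0.7) +
    geom_segment(data = tibble(phase = (cs$mean_direction + 360) %% 360,
                               r = cs$r),
                 aes(x = .data$phase, xend = .data$phase, y = 0,
                     yend = .data$r),
                 arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                 colour = "red") +
    coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270)) +
    ggplot2::ylim(0, 1.1) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Iso-sensitivity plot of the X_max model
#'
#' Contours of constant `X_max = R * r^2` over the lumen-radius x
#' circuit-radius plane, with optional specimen points overlaid.
#'
#' @param specimens optional tibble with columns `r`, `R` and a label
#'   column `species`.
#' @inheritParams xmax_grid
#' @return A ggplot.
#' @export
plot_xmax_curves <- function(specimens = NULL, r_range = c(20, 120),
                             R_range = c(300, 800)) {
  g <- xmax_grid(r_range, R_range)
  p <- ggplot(g, aes(x = .data$r, y = .data$R, z = .data$xmax)) +
    geom_contour(colour = "grey40", bins = 12) +
    labs(x = expression(lumen ~ radius ~ r ~ (mu * m)),
         y = expression(circuit ~ radius ~ R ~ (mu * m))) +
    theme_minimal()
  if (!is.null(specimens)) {
    p <- p + geom_point(data = specimens,
                        aes(x = .data$r, y = .data$R,
                            colour = .data$species),
                        inherit.aes = FALSE, size = 3)
  }
  p
}

#' Variance-scaled loading heat map
#'
#' @param components an `avg_components` (see [average_components()]).
#' @param n_components how many components to show.
#' @return A ggplot.
#' @export
plot_loading_map <- function(components, n_components = 5) {
  lm_df <- loading_map(components)
  keep <- colnames(components$rotation)[
    seq_len(min(n_components, ncol(components$rotation)))]
  lm_df <- lm_df[lm_df$component %in% keep, ]
  lm_df$variable <- factor(lm_df$variable,
                           levels = rev(rownames(components$rotation)))
  ggplot(lm_df, aes(x = .data$component, y = .data$variable,
                    fill = .data$scaled)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = NULL, y = NULL, fill = "loading x var") +
    theme_minimal()
}
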