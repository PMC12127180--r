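#' Compute locomotor kinematics from a landmark trajectory
#'
#' Converts the six-landmark pixel trajectory into the locomotor metric
#' series: body-centre speed (mm/s) and cumulative distance (mm), tail
#' deflection angle (degrees, between the skull-to-centre-of-mass axis and
#' the centre-of-mass-to-tail axis) and its velocity, head angle (left-eye to
#' right-eye line vs the image horizontal) and head angular acceleration.
#' Speed and tail velocity are Savitzky-Golay smoothed (window 15, order 3);
#' derivatives are central differences on the native frame grid, with angular
#' acceleration from the central second difference.
#'
#' @param traj a [landmark_trajectory].
#' @param tail_point which tail landmark defines the tail axis
#'   (`"tail1"`, the default, or `"tail2"`).
#' @param sg_window,sg_order Savitzky-Golay smoothing window (frames, odd)
#'   and polynomial order.
#' @return A `kinematics_series` tibble: `time`, `x_mm`, `y_mm`,
#'   `swim_speed`, `cumulative_distance`, `tail_angle`, `tail_velocity`,
#'   `head_angle`, `head_ang_accel`.
#' @export
compute_kinematics <- function(traj, tail_point = c("tail1", "tail2"),
                               sg_window = 15, sg_order = 3) {
  stopifnot(inherits(traj, "landmark_trajectory"))
  tail_point <- match.arg(tail_point)
  n <- nrow(traj)
  if (n < sg_window) {
    abort(sprintf("trajectory has %d frames; at least %d needed for smoothing",
                  n, sg_window), class = "gazestab_input_error")
  }
  fps <- attr(traj, "frame_rate")
  scale <- attr(traj, "pixel_scale")

  com <- cbind(traj$body_com_x, traj$body_com_y) * scale
  skull <- cbind(traj$skull_center_x, traj$skull_center_y) * scale
  tailp <- cbind(traj[[paste0(tail_point, "_x")]],
                 traj[[paste0(tail_point, "_y")]]) * scale

  step <- sqrt(rowSums(diff(com)^2))                 # mm per frame
  speed_raw <- c(step[1], step) * fps
  cumdist <- c(0, cumsum(step))

  # signed angle between the (skull -> com) axis and the (com -> tail) axis
  ax1 <- com - skull
  ax2 <- tailp - com
  tail_angle <- atan2(ax1[, 1] * ax2[, 2] - ax1[, 2] * ax2[, 1],
                      rowSums(ax1 * ax2)) * 180 / pi
  tail_vel_raw <- central_diff(tail_angle) * fps

  swim_speed <- signal::sgolayfilt(speed_raw, p = sg_order, n = sg_window)
  tail_velocity <- signal::sgolayfilt(tail_vel_raw, p = sg_order, n = sg_window)

  de <- cbind(traj$right_eye_x - traj$left_eye_x,
              traj$right_eye_y - traj$left_eye_y)
  head_angle <- unwrap_deg(atan2(de[, 2], de[, 1]) * 180 / pi)
  head_ang_accel <- second_diff(head_angle) * fps^2

  structure(
    tibble(time = traj$time, x_mm = com[, 1], y_mm = com[, 2],
           swim_speed = swim_speed, cumulative_distance = cumdist,
           tail_angle = tail_angle, tail_velocity = tail_velocity,
           head_angle = head_angle, head_ang_accel = head_ang_accel),
    frame_rate = fps,
    class = c("kinematics_series", class(tibble())))
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1]
  d
}

second_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]
  d[1] <- d[2]
  d[n] <- d[n - 1]
  d
}

unwrap_deg <- function(theta) {
  d <- diff(theta)
  jump <- cumsum(c(0, -360 * (d > 180) + 360 * (d < -180)))
  theta + jump
}

#' Detect active swim bouts by dual thresholding
#'
#' A frame is active iff the smoothed swim speed exceeds `v_thresh` *and* the
#' absolute smoothed tail velocity exceeds `tail_thresh` (both strict),
#' excluding tail wiggling without locomotion as well as passive drift or
#' glides. Maximal runs of active frames become bouts.
#'
#' @param kin a `kinematics_series` from [compute_kinematics()].
#' @param v_thresh swim-speed threshold, mm/s (default 3).
#' @param tail_thresh tail-velocity threshold, degrees/s (default 3).
#' @param bridge_frames inactive gaps of at most this many frames between
#'   active runs are bridged (default 1). At 30 frames/s a one-frame gap is
#'   far shorter than any physiological pause and arises only when a sample
#'   lands on a zero crossing of the smoothed tail velocity; set to 0 for
#'   strict maximal runs.
#' @return A tibble of disjoint ordered bouts: `bout`, `start`, `end`,
#'   `duration` (s; `end` is exclusive, so `duration = end - start`).
#' @export
detect_bouts <- function(kin, v_thresh = 3, tail_thresh = 3,
                         bridge_frames = 1) {
  stopifnot(inherits(kin, "kinematics_series"), v_thresh > 0, tail_thresh > 0)
  fps <- attr(kin, "frame_rate")
  active <- kin$swim_speed > v_thresh & abs(kin$tail_velocity) > tail_thresh
  if (bridge_frames > 0) {
    r0 <- rle(active)
    gap <- !r0$values & r0$lengths <= bridge_frames
    inner <- seq_along(gap) > 1 & seq_along(gap) < length(gap)
    r0$values[gap & inner] <- TRUE
    active <- inverse.rle(r0)
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  tibble(bout = seq_along(on),
         start = kin$time[starts[on]],
         end = kin$time[ends[on]] + 1 / fps,
         duration = r$lengths[on] / fps)
}

#' Summarise swim bouts with duration-weighted densities
#'
#' Percent time swimming and a probability density of bout durations in
#' which each bout is weighted by its own duration, so a 30 s bout
#' contributes 30 times the mass of a 1 s bout.
#'
#' @param bouts a bout tibble from [detect_bouts()].
#' @param recording_length recording duration, s (must cover all bouts).
#' @param bin_width histogram bin width for the weighted density, s.
#' @return A `bout_summary` object; [glance()] gives the one-row summary
#'   (`n_bouts`, `total_swim_time`, `percent_time_swimming`,
#'   `mean_duration`), [tidy()] the weighted density bins.
#' @export
summarize_bouts <- function(bouts, recording_length, bin_width = 0.5) {
  if (nrow(bouts) > 0 && recording_length < max(bouts$end)) {
    abort("recording_length is shorter than the last bout",
          class = "gazestab_input_error")
  }
  if (nrow(bouts) == 0) {
    dens <- tibble(bin_lower = numeric(), bin_upper = numeric(),
                   density = numeric())
    out <- list(n_bouts = 0L, total_swim_time = 0,
                percent_time_swimming = 0, mean_duration = NA_real_,
                density = dens)
    return(structure(out, class = "bout_summary"))
  }
  durs <- bouts$duration
  total <- sum(durs)
  edges <- seq(0, ceiling(max(durs) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2) edges <- c(0, bin_width)
  idx <- findInterval(durs, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  w <- vapply(seq_len(length(edges) - 1),
              function(b) sum(durs[idx == b]), numeric(1))
  dens <- tibble(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
                 density = w / (sum(w) * bin_width))
  structure(list(n_bouts = nrow(bouts), total_swim_time = total,
                 percent_time_swimming = 100 * total / recording_length,
                 mean_duration = mean(durs), density = dens),
            class = "bout_summary")
}

#' @export
print.bout_summary <- function(x, ...) {
  cat(sprintf("<bout_summary> %d bouts, %.2f s swimming (%.1f%% of recording)\n",
              x$n_bouts, x$total_swim_time, x$percent_time_swimming))
  invisible(x)
}

#' @rdname summarize_bouts
#' @param x a `bout_summary`.
#' @param ... unused.
#' @export
glance.bout_summary <- function(x, ...) {
  tibble(n_bouts = x$n_bouts, total_swim_time = x$total_swim_time,
         percent_time_swimming = x$percent_time_swimming,
         mean_duration = x$mean_duration)
}

#' @rdname summarize_bouts
#' @export
tidy.bout_summary <- function(x, ...) x$density

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two pooled samples (e.g. head angular accelerations of two
#' species) by the supremum distance between their empirical CDFs, with the
#' two-sided asymptotic p-value.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return A one-row tibble: `statistic`, `p.value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("both samples must be non-empty", class = "gazestab_input_error")
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  tibble(statistic = unname(kt$statistic), p.value = kt$p.value,
         n_a = length(sample_a), n_b = length(sample_b))
}
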