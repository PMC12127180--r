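#' Published stage-54 condition presets
#'
#' Bundles the stage-54 group means for both species — reflex gains and
#' phases, per-minute swim time, weighted mean bout duration, canal radii and
#' duct length — as a single source of truth for generator presets and
#' recovery checks. Phases follow the convention negative = lead.
#'
#' @param species `"xenopus_54"` or `"axolotl_54"`.
#' @return A named list of condition means (gains dimensionless, phases in
#'   degrees, times in s, radii in micrometres, duct length in mm).
#' @export
species_preset <- function(species = c("xenopus_54", "axolotl_54")) {
  species <- match.arg(species)
  presets <- list(
    xenopus_54 = list(
      vor_dark  = c(gain = 0.29, phase = -54.3),
      vor_light = c(gain = 0.32, phase = -29.4),
      okr       = c(gain = 0.14, phase = 13.4),
      eye_tail_ratio   = 90.31,   # % of tail cycles with a coupled eye cycle
      swim_time_per_60s = 28.8,   # s actively swimming per 60 s recording
      bout_duration    = 6.98,    # s, duration-weighted mean bout length
      circuit_radius   = 634.09,  # um
      lumen_radius     = 77.11,   # um
      duct_length_mm   = 1.4
    ),
    axolotl_54 = list(
      vor_dark  = c(gain = 0.05, phase = 47.06),
      vor_light = c(gain = 0.14, phase = 41.52),
      okr       = c(gain = 0.25, phase = 6.03),
      eye_tail_ratio   = 56.49,
      swim_time_per_60s = 10.7,
      bout_duration    = 0.92,
      circuit_radius   = 582.91,
      lumen_radius     = 66.32,
      duct_length_mm   = 1.07
    )
  )
  presets[[species]]
}

#' Swim-trajectory simulation settings
#'
#' @param duration recording length, s.
#' @param frame_rate frames per second.
#' @param bout_schedule two-column matrix/data frame (start, duration in s) of
#'   scripted bouts, or `NULL` to draw a stochastic burst-and-glide schedule.
#' @param n_bouts,bout_mean,gap_mean stochastic schedule: number of bouts,
#'   mean bout duration (exponential), mean inter-bout gap (exponential).
#'   Used only when `bout_schedule` is `NULL`.
#' @param swim_speed forward speed during bouts, mm/s.
#' @param glide logical; append an exponential coast after each bout.
#' @param glide_tau glide velocity decay time constant, s.
#' @param tail_beat_freq tail undulation frequency during bouts, Hz.
#' @param tail_amplitude tail deflection half-amplitude, degrees.
#' @param head_yaw_amplitude head yaw half-amplitude during bouts, degrees.
#' @param tail_taper_s duration of the cosine decay of the tail-beat and
#'   thrust envelope at the end of each bout, s; the final stroke dies out
#'   rather than stopping instantaneously. Onset uses a fixed 0.07 s
#'   build-up (explosive first stroke).
#' @param noise_sd landmark jitter SD, mm (sub-pixel tracker noise).
#' @param pixel_scale mm per pixel of the emulated video.
#' @return A `swim_sim_config` list.
#' @export
swim_config <- function(duration = 60, frame_rate = 30,
                        bout_schedule = NULL,
                        n_bouts = 6, bout_mean = 3, gap_mean = 5,
                        swim_speed = 5, glide = FALSE, glide_tau = 0.3,
                        tail_beat_freq = 4, tail_amplitude = 25,
                        head_yaw_amplitude = 8,
                        tail_taper_s = 0.15,
                        noise_sd = 0.02,
                        pixel_scale = 0.157) {
  stopifnot(duration > 0, frame_rate > 0, swim_speed >= 0,
            tail_beat_freq > 0, glide_tau > 0, pixel_scale > 0)
  if (!is.null(bout_schedule)) {
    bout_schedule <- as.matrix(bout_schedule)[, 1:2, drop = FALSE]
    colnames(bout_schedule) <- c("start", "duration")
    ends <- bout_schedule[, 1] + bout_schedule[, 2]
    ord <- order(bout_schedule[, 1])
    bout_schedule <- bout_schedule[ord, , drop = FALSE]
    ends <- ends[ord]
    if (any(bout_schedule[, 1] < 0) || any(ends > duration)) {
      abort("bout schedule extends outside [0, duration]",
            class = "gazestab_config_error")
    }
    if (nrow(bout_schedule) > 1 &&
        any(bout_schedule[-1, 1] < ends[-length(ends)])) {
      abort("bouts overlap", class = "gazestab_config_error")
    }
  }
  structure(list(duration = duration, frame_rate = frame_rate,
                 bout_schedule = bout_schedule, n_bouts = n_bouts,
                 bout_mean = bout_mean, gap_mean = gap_mean,
                 swim_speed = swim_speed, glide = glide,
                 glide_tau = glide_tau, tail_beat_freq = tail_beat_freq,
                 tail_amplitude = tail_amplitude,
                 head_yaw_amplitude = head_yaw_amplitude,
                 tail_taper_s = tail_taper_s,
                 noise_sd = noise_sd, pixel_scale = pixel_scale),
            class = "swim_sim_config")
}

#' Species swim presets
#'
#' Scripted bout schedules reproducing the published per-minute swim budgets:
#' the Xenopus preset swims in 4 long bouts (7.2 s each, totalling 28.8 s per
#' 60 s, near the published duration-weighted bout mean of ~7 s); the axolotl
#' preset swims in 12 sub-second bursts (10.7/12 s each, totalling 10.7 s)
#' each followed by a passive glide.
#'
#' @inheritParams species_preset
#' @return A [swim_config()] object.
#' @export
swim_preset <- function(species = c("xenopus_54", "axolotl_54")) {
  species <- match.arg(species)
  p <- species_preset(species)
  if (species == "xenopus_54") {
    starts <- c(3, 18, 33, 48)
    durs <- rep(p$swim_time_per_60s / 4, 4)     # 4 x 7.2 s
    swim_config(bout_schedule = cbind(starts, durs), glide = FALSE)
  } else {
    n <- 12
    durs <- rep(p$swim_time_per_60s / n, n)     # 12 x ~0.89 s
    starts <- seq(2, by = 4.7, length.out = n)
    swim_config(bout_schedule = cbind(starts, durs), glide = TRUE)
  }
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Simulate a pose-tracked swim recording
#'
#' Generates a six-landmark trajectory: the body centre of mass advances at
#' `swim_speed` during scheduled bouts (with optional exponential glide
#' afterwards), the tail points oscillate at `tail_beat_freq`, and the head
#' (eye line) yaws sinusoidally. Between bouts the animal is stationary up to
#' tracker jitter. Ground-truth bout intervals are attached as the
#' `ground_truth` attribute.
#'
#' @param config a [swim_config()] (or [swim_preset()]).
#' @param seed integer seed for the schedule and jitter.
#' @return A [landmark_trajectory] with attribute `ground_truth`, a tibble of
#'   the scripted bouts (`start`, `end`, `duration` in s).
#' @export
simulate_swim <- function(config = swim_config(), seed = 1) {
  stopifnot(inherits(config, "swim_sim_config"))
  set.seed(seed)
  fps <- config$frame_rate
  n <- round(config$duration * fps)
  t <- (seq_len(n) - 1) / fps

  sched <- config$bout_schedule
  if (is.null(sched)) {
    durs <- stats::rexp(config$n_bouts, 1 / config$bout_mean)
    gaps <- stats::rexp(config$n_bouts, 1 / config$gap_mean) + 0.5
    starts <- cumsum(gaps + dplyr::lag(durs, default = 0))
    keep <- (starts + durs) <= config$duration - 0.5
    sched <- cbind(start = starts[keep], duration = durs[keep])
    if (nrow(sched) == 0) {
      abort("stochastic schedule produced no bouts inside the recording",
            class = "gazestab_config_error")
    }
  }
  bouts <- tibble(start = sched[, 1], end = sched[, 1] + sched[, 2],
                  duration = sched[, 2])

  # per-frame forward speed (mm/s) and tail/yaw phase
  speed <- numeric(n)
  tail_angle <- numeric(n)
  yaw <- numeric(n)
  onset_s <- 0.07
  for (b in seq_len(nrow(bouts))) {
    act <- t >= bouts$start[b] & t < bouts$end[b]
    ph <- 2 * pi * config$tail_beat_freq * (t - bouts$start[b])
    # build-up over the first stroke, final stroke dying out over the taper
    taper_s <- min(config$tail_taper_s, bouts$duration[b] / 4)
    up <- pmin(1, pmax(0, (t - bouts$start[b]) / onset_s))
    down <- pmin(1, pmax(0, (bouts$end[b] - t) / max(taper_s, 1e-9)))
    env <- 0.5 * (1 - cos(pi * up)) * 0.5 * (1 - cos(pi * down))
    tail_angle[act] <- config$tail_amplitude * env[act] * sin(ph[act])
    yaw[act] <- config$head_yaw_amplitude * env[act] * sin(ph[act])
    if (config$glide) {
      # thrust ends with the last full-power stroke; the body then coasts
      # (passive drag decay) through the dying stroke and beyond
      t_coast <- bouts$end[b] - taper_s
      seg <- t >= bouts$start[b] &
        (if (b == nrow(bouts)) TRUE else t < bouts$start[b + 1])
      v_env <- config$swim_speed * 0.5 * (1 - cos(pi * up))
      v_coast <- ifelse(t >= t_coast,
                        config$swim_speed * exp(-(t - t_coast) /
                                                  config$glide_tau), 0)
      speed[seg] <- pmax(speed[seg],
                         ifelse(t < t_coast, v_env, v_coast)[seg])
    } else {
      # active stop: speed follows the stroke envelope at both edges
      v_up <- 0.5 * (1 - cos(pi * up))
      v_down <- 0.5 * (1 - cos(pi * down))
      speed[act] <- config$swim_speed * (v_up * v_down)[act]
    }
  }

  # heading: fixed per bout (drawn once), so the path is piecewise straight
  heading <- numeric(n)
  hb <- runif(nrow(bouts), 0, 2 * pi)
  cur <- 0
  for (b in seq_len(nrow(bouts))) {
    heading[t >= bouts$start[b]] <- hb[b]
  }
  # integrate position (mm), starting at the dish centre
  step <- speed / fps
  com <- cbind(cumsum(step * cos(heading)), cumsum(step * sin(heading)))
  com <- sweep(com, 2, c(94, 94), "+")   # ~centre of an 18.8 cm dish

  # rigid body frame: skull ahead of com, tail points behind, deflected
  L_head <- 4; L_eye <- 2.5; L_t1 <- 6; L_t2 <- 10   # mm
  u <- cbind(cos(heading), sin(heading))              # forward unit vector
  skull <- com + L_head * u
  tail_dir <- heading + pi + tail_angle * pi / 180
  tail1 <- com + L_t1 * cbind(cos(tail_dir), sin(tail_dir))
  tail2 <- com + L_t2 * cbind(cos(tail_dir), sin(tail_dir))
  eye_dir <- heading + pi / 2 + yaw * pi / 180
  ev <- cbind(cos(eye_dir), sin(eye_dir))
  left_eye <- skull + L_eye * ev
  right_eye <- skull - L_eye * ev

  jitter <- function(m) m + matrix(rnorm(2 * n, 0, config$noise_sd), n, 2)
  px <- function(m) jitter(m) / config$pixel_scale
  coords <- tibble(
    left_eye_x = px(left_eye)[, 1],  left_eye_y = px(left_eye)[, 2],
    right_eye_x = px(right_eye)[, 1], right_eye_y = px(right_eye)[, 2],
    skull_center_x = px(skull)[, 1], skull_center_y = px(skull)[, 2],
    body_com_x = px(com)[, 1],       body_com_y = px(com)[, 2],
    tail1_x = px(tail1)[, 1],        tail1_y = px(tail1)[, 2],
    tail2_x = px(tail2)[, 1],        tail2_y = px(tail2)[, 2]
  )
  traj <- landmark_trajectory(coords, frame_rate = fps,
                              pixel_scale = config$pixel_scale)
  attr(traj, "ground_truth") <- bouts
  traj
}

#' Eye-response simulation settings
#'
#' @param gain response gain (>= 0), peak-to-peak eye / peak-to-peak stimulus.
#' @param phase response phase in degrees, in (-180, 180], negative = lead.
#' @param stimulus_freq stimulus frequency, Hz.
#' @param stimulus_amplitude positional half-excursion, degrees.
#' @param n_cycles number of stimulus cycles to generate.
#' @param sample_rate samples per second.
#' @param noise_sd additive eye-position noise SD, degrees (white at the
#'   sample rate).
#' @param fast_phase_rate resetting fast phases per minute (0 = none).
#' @param stimulus_kind `"vestibular_dark"`, `"vestibular_light"` (eye
#'   compensatory, i.e. anti-phase to the stimulus) or `"visual"` (eye
#'   following the stimulus).
#' @return An `eye_sim_config` list.
#' @export
eye_config <- function(gain = 0.29, phase = 0, stimulus_freq = 0.5,
                       stimulus_amplitude = 10, n_cycles = 20,
                       sample_rate = 200, noise_sd = 0,
                       fast_phase_rate = 0,
                       stimulus_kind = c("vestibular_dark",
                                         "vestibular_light", "visual")) {
  stimulus_kind <- match.arg(stimulus_kind)
  stopifnot(gain >= 0, phase > -180, phase <= 180, stimulus_freq > 0,
            n_cycles >= 2, sample_rate > 0, noise_sd >= 0,
            fast_phase_rate >= 0)
  structure(as.list(environment()), class = "eye_sim_config")
}

#' Simulate a sinusoidal stimulus/eye trace
#'
#' The stimulus is `A sin(2 pi f t)`. The eye follows (visual) or opposes
#' (vestibular) it at the configured gain, shifted by the configured phase
#' (negative = lead), with optional Gaussian noise and resetting fast phases
#' modelled as 100 ms linear position jumps against the ongoing slow-phase
#' direction.
#'
#' @param config an [eye_config()].
#' @param seed integer seed (noise and fast-phase times).
#' @return A [motion_trace] (two identical-statistics eyes) with attribute
#'   `ground_truth` (`gain`, `phase`, fast-phase times).
#' @export
simulate_eyes <- function(config = eye_config(), seed = 1) {
  stopifnot(inherits(config, "eye_sim_config"))
  set.seed(seed)
  f <- config$stimulus_freq
  A <- config$stimulus_amplitude
  dur <- config$n_cycles / f
  n <- round(dur * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  stim <- A * sin(2 * pi * f * t)
  dir <- if (config$stimulus_kind == "visual") 1 else -1
  slow <- dir * config$gain * A * sin(2 * pi * f * t - config$phase * pi / 180)

  fp_times <- numeric(0)
  offset <- numeric(n)
  if (config$fast_phase_rate > 0) {
    n_fp <- stats::rpois(1, config$fast_phase_rate * dur / 60)
    fp_times <- sort(runif(n_fp, 2 / f, dur - 2 / f))
    slow_vel <- c(diff(slow), 0) * config$sample_rate
    for (ft in fp_times) {
      i0 <- which.min(abs(t - ft))
      # resetting saccade sweeping ~the ocular range, against the slow phase
      amp <- -sign(slow_vel[i0] + 1e-12) * 3 * A
      ramp_len <- max(2L, round(0.1 * config$sample_rate))   # 100 ms
      idx <- i0:min(n, i0 + ramp_len - 1)
      offset[idx] <- offset[idx] + amp * seq_along(idx) / ramp_len
      if (max(idx) < n) offset[(max(idx) + 1):n] <-
          offset[(max(idx) + 1):n] + amp
    }
  }
  mk_eye <- function() slow + offset + rnorm(n, 0, config$noise_sd)
  tr <- motion_trace(t, stim, mk_eye(), mk_eye(),
                     sample_rate = config$sample_rate,
                     stimulus_kind = config$stimulus_kind,
                     stimulus_freq = f, stimulus_amplitude = A)
  attr(tr, "ground_truth") <- list(gain = config$gain, phase = config$phase,
                                   fast_phase_times = fp_times)
  tr
}

#' Simulate a paired eye-tail trace (head-fixed swimming)
#'
#' The tail oscillates for `n_cycles` with per-cycle amplitudes jittered
#' around `tail_amplitude`; a random `coupled_fraction` of cycles carry an
#' opposite-direction eye excursion scaled by the spino-ocular gain, which
#' may decline linearly with tail amplitude (`gain_slope`).
#'
#' @param n_cycles number of tail cycles.
#' @param coupled_fraction fraction of tail cycles with a coupled eye cycle.
#' @param tail_amplitude mean peak-to-peak tail amplitude, degrees.
#' @param gain spino-ocular gain at the mean tail amplitude.
#' @param gain_slope change in gain per degree of peak-to-peak amplitude.
#' @param tail_freq tail beat frequency, Hz.
#' @param sample_rate samples per second.
#' @param noise_sd additive noise SD on both traces, degrees.
#' @param seed integer seed.
#' @return A tibble (`time`, `tail`, `eye`; degrees) of class
#'   `eyetail_trace` with attribute `ground_truth` (per-cycle table and the
#'   programmed coupled fraction).
#' @export
simulate_eye_tail <- function(n_cycles = 100, coupled_fraction = 0.9,
                              tail_amplitude = 20, gain = 0.3,
                              gain_slope = 0, tail_freq = 4,
                              sample_rate = 250, noise_sd = 0, seed = 1) {
  stopifnot(coupled_fraction >= 0, coupled_fraction <= 1, n_cycles >= 1)
  set.seed(seed)
  spc <- round(sample_rate / tail_freq)          # samples per cycle
  n <- n_cycles * spc
  t <- (seq_len(n) - 1) / sample_rate
  amp <- tail_amplitude * runif(n_cycles, 0.7, 1.3)   # peak-to-peak
  n_coupled <- round(coupled_fraction * n_cycles)
  coupled <- seq_len(n_cycles) %in% sample(n_cycles, n_coupled)
  g <- pmax(0, gain + gain_slope * (amp - tail_amplitude))

  cyc <- rep(seq_len(n_cycles), each = spc)
  ph <- 2 * pi * ((seq_len(n) - 1) %% spc) / spc
  tail <- (amp[cyc] / 2) * sin(ph)
  eye <- ifelse(coupled[cyc], -g[cyc] * tail, 0)
  tail <- tail + rnorm(n, 0, noise_sd)
  eye <- eye + rnorm(n, 0, noise_sd)

  out <- tibble(time = t, tail = tail, eye = eye)
  out <- structure(out, sample_rate = sample_rate, tail_freq = tail_freq,
                   class = c("eyetail_trace", class(tibble())))
  attr(out, "ground_truth") <- list(
    cycles = tibble(cycle = seq_len(n_cycles), amplitude = amp,
                    coupled = coupled, gain = ifelse(coupled, g, NA_real_)),
    coupled_fraction = n_coupled / n_cycles)
  out
}

#' Canal-phantom simulation settings
#'
#' @param semi_axes `(a, b)` semi-axes of the duct circuit ellipse, um.
#' @param tube_radius duct lumen radius, um.
#' @param arc_span swept angle of the torus segment, degrees (360 = closed).
#' @param out_of_plane_tilt tilt of the canal plane about the x axis, degrees.
#' @param ampulla_scale bulge factor (> 1) applied to the tube radius over
#'   the final 15% of arc (Gaussian profile); 1 = no ampulla.
#' @param stenosis optional `c(position, factor)`: a localized constriction
#'   (tube radius multiplied by `factor` in (0,1)) centred at the normalized
#'   arclength `position`.
#' @param voxel_size isotropic voxel spacing, um.
#' @param blur_sigma Gaussian blur in voxels applied to the binary phantom
#'   (0 = crisp binary output).
#' @param noise_sd additive grayscale noise SD (fraction of signal).
#' @return A `canal_phantom_config` list.
#' @export
canal_config <- function(semi_axes = c(600, 600), tube_radius = 66,
                         arc_span = 360, out_of_plane_tilt = 0,
                         ampulla_scale = 1, stenosis = NULL,
                         voxel_size = 3, blur_sigma = 0, noise_sd = 0) {
  stopifnot(length(semi_axes) == 2, semi_axes[1] >= semi_axes[2],
            semi_axes[2] > tube_radius, tube_radius > 0,
            arc_span > 0, arc_span <= 360, ampulla_scale >= 1,
            voxel_size > 0)
  if (!is.null(stenosis)) {
    stopifnot(length(stenosis) == 2, stenosis[1] >= 0, stenosis[1] <= 1,
              stenosis[2] > 0, stenosis[2] < 1)
  }
  structure(as.list(environment()), class = "canal_phantom_config")
}

# tube radius as a function of normalized arclength s in [0, 1]
phantom_radius_profile <- function(config, s) {
  r <- rep(config$tube_radius, length(s))
  if (config$ampulla_scale > 1) {
    # Gaussian bulge centred at the far end, ~15% of arc wide
    r <- r * (1 + (config$ampulla_scale - 1) * exp(-0.5 * ((s - 1) / 0.075)^2))
  }
  if (!is.null(config$stenosis)) {
    pos <- config$stenosis[1]; fac <- config$stenosis[2]
    dip <- (1 - fac) * exp(-0.5 * ((s - pos) / 0.015)^2)
    r <- r * (1 - dip)
  }
  r
}

#' Simulate a voxelized semicircular-canal phantom
#'
#' Voxelizes an elliptic-torus segment with optional ampulla bulge,
#' out-of-plane tilt and pre-ampullary stenosis, and attaches the analytic
#' ground truth (centerline length, cross-section area profile, stenosis
#' ratio, circuit-ellipse axes).
#'
#' @param config a [canal_config()].
#' @return A binary (or blurred grayscale) [canal_volume] with attribute
#'   `ground_truth`.
#' @export
simulate_canal <- function(config = canal_config()) {
  stopifnot(inherits(config, "canal_phantom_config"))
  a <- config$semi_axes[1]; b <- config$semi_axes[2]
  vox <- config$voxel_size
  if (config$tube_radius < 2 * vox) {
    abort("tube radius below 2 voxels; refine the voxel size",
          class = "gazestab_resolution_error")
  }
  span <- config$arc_span * pi / 180
  closed <- config$arc_span >= 360 - 1e-9
  th0 <- -span / 2
  th <- seq(th0, th0 + span, length.out = max(2000, ceiling(span * a / vox)))

  # analytic centerline and arclength
  cl <- cbind(a * cos(th), b * sin(th), 0)
  seglen <- sqrt(rowSums(diff(cl)^2))
  arclen <- c(0, cumsum(seglen))
  total_len <- arclen[length(arclen)]
  s_norm <- arclen / total_len
  r_prof <- phantom_radius_profile(config, s_norm)
  rmax <- max(r_prof)

  tilt <- config$out_of_plane_tilt * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(tilt), sin(tilt),
                 0, -sin(tilt), cos(tilt)), 3, 3, byrow = TRUE)
  clw <- cl %*% t(Rx)

  pad <- rmax + 3 * vox
  lim <- apply(clw, 2, range)
  xr <- seq(lim[1, 1] - pad, lim[2, 1] + pad, by = vox)
  yr <- seq(lim[1, 2] - pad, lim[2, 2] + pad, by = vox)
  zr <- seq(lim[1, 3] - pad, lim[2, 3] + pad, by = vox)
  d <- c(length(zr), length(yr), length(xr))

  # world voxel centres -> canal frame (inverse tilt), vectorized
  grid_z <- rep(zr, times = d[2] * d[3])
  grid_y <- rep(rep(yr, each = d[1]), times = d[3])
  grid_x <- rep(xr, each = d[1] * d[2])
  cx <- grid_x
  cy <- cos(tilt) * grid_y + sin(tilt) * grid_z
  cz <- -sin(tilt) * grid_y + cos(tilt) * grid_z

  # prefilter: keep voxels near the elliptic annulus and the canal plane
  e <- sqrt((cx / a)^2 + (cy / b)^2)
  keep <- which(abs(cz) <= rmax + 2 * vox &
                  b * abs(e - 1) <= 1.8 * (rmax + 2 * vox))
  inside <- logical(length(grid_x))
  if (length(keep) > 0) {
    phi <- atan2(cy[keep] / b, cx[keep] / a)
    best <- rep(Inf, length(keep))
    best_s <- rep(0, length(keep))
    for (dphi in seq(-0.08, 0.08, by = 0.016)) {
      ang <- phi + dphi
      if (closed) {
        angc <- ang
      } else {
        # clamp into the swept interval (handle wrap)
        rel <- (ang - th0) %% (2 * pi)
        angc <- th0 + pmin(rel, span)
      }
      px <- a * cos(angc); py <- b * sin(angc)
      dd <- sqrt((cx[keep] - px)^2 + (cy[keep] - py)^2 + cz[keep]^2)
      upd <- dd < best
      best[upd] <- dd[upd]
      ss <- ((angc - th0) %% (2 * pi)) / span
      best_s[upd] <- pmin(1, ss[upd])
    }
    rloc <- phantom_radius_profile(config, best_s)
    ok <- best <= rloc
    if (!closed) {
      # blunt (flat) duct ends, as in a cropped segmentation: cut on the
      # plane perpendicular to the centerline at each arc endpoint; the cut
      # applies only near its own end (for spans > 180 deg the half-space
      # would otherwise clip the opposite end of the arc)
      for (endp in list(list(th = th0, sgn = -1, near = best_s <= 0.05),
                        list(th = th0 + span, sgn = 1, near = best_s >= 0.95))) {
        tx <- -a * sin(endp$th); ty <- b * cos(endp$th)
        tn <- sqrt(tx^2 + ty^2)
        proj <- ((cx[keep] - a * cos(endp$th)) * tx +
                   (cy[keep] - b * sin(endp$th)) * ty) / tn
        ok <- ok & !(endp$near & endp$sgn * proj > 0)
      }
    }
    inside[keep] <- ok
  }
  volarr <- array(0, dim = d)
  volarr[inside] <- 1
  if (sum(inside) == 0) {
    abort("phantom produced an empty volume", class = "gazestab_config_error")
  }

  if (config$blur_sigma > 0) {
    volarr <- array(cpp_blur3d(as.numeric(volarr), d, config$blur_sigma),
                    dim = d)
  }
  if (config$noise_sd > 0) {
    volarr <- volarr + array(rnorm(length(volarr), 0, config$noise_sd), d)
    volarr <- pmin(pmax(volarr, 0), 1)   # first-arg order keeps dim()
  }
  out <- canal_volume(volarr, vox,
                      is_binary = config$blur_sigma == 0 && config$noise_sd == 0)

  n_s <- 200
  s_grid <- seq(0, 1, length.out = n_s)
  r_s <- phantom_radius_profile(config, s_grid)
  cs <- pi * r_s^2
  attr(out, "ground_truth") <- list(
    centerline_length = total_len,
    cs_profile = tibble(s = s_grid, area = cs),
    cs_mean = mean(cs), cs_min = min(cs),
    stenosis_ratio = min(cs) / mean(cs),
    stenosis_position = s_grid[which.min(cs)],
    circuit_axes = c(a = a, b = b),
    circuit_radius = sqrt((a^2 + b^2) / 2),
    tube_radius = config$tube_radius,
    closed = closed)
  out
}
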