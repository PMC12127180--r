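#' Resample and low-pass filter a stimulus/eye trace
#'
#' Resamples all channels to a uniform 200 samples/s, applies a zero-lag
#' (forward-backward) 4th-order Butterworth low-pass at 4 Hz, and, when both
#' eyes are present, adds their conjugate average as the analysis channel.
#' Zero-lag filtering keeps the phase metric unbiased; reflection padding
#' suppresses the filter's edge transients.
#'
#' @param trace a [motion_trace].
#' @param target_rate output sample rate, samples/s.
#' @param cutoff low-pass corner frequency, Hz.
#' @param order Butterworth order.
#' @return A [motion_trace] at `target_rate` with an `eye` column (the
#'   conjugate average, or the single eye).
#' @export
preprocess <- function(trace, target_rate = 200, cutoff = 4, order = 4) {
  stopifnot(inherits(trace, "motion_trace"))
  f <- attr(trace, "stimulus_freq")
  dur <- max(trace$time) - min(trace$time)
  if (dur < 2 / f) {
    abort("trace shorter than two stimulus cycles",
          class = "gazestab_input_error")
  }
  tnew <- seq(min(trace$time), max(trace$time), by = 1 / target_rate)
  if (length(tnew) < 6 * (order + 1)) {
    abort("trace shorter than the filter warm-up", class = "gazestab_input_error")
  }
  bf <- signal::butter(order, cutoff / (target_rate / 2))
  res <- function(v) {
    u <- approx(trace$time, v, xout = tnew)$y
    filtfilt_padded(bf, u)
  }
  stim <- res(trace$stimulus)
  el <- res(trace$eye_left)
  er <- if ("eye_right" %in% names(trace)) res(trace$eye_right) else NULL
  out <- motion_trace(tnew, stim, el, er,
                      sample_rate = target_rate,
                      stimulus_kind = attr(trace, "stimulus_kind"),
                      stimulus_freq = f,
                      stimulus_amplitude = attr(trace, "stimulus_amplitude"))
  out$eye <- if (is.null(er)) el else (el + er) / 2
  # pre-filter eye velocity on a 50 ms base: resetting fast phases live
  # above the low-pass corner, so jerk screening must look at the
  # unfiltered signal, but a sample-to-sample derivative would only
  # amplify tracker noise
  raw <- approx(trace$time, trace$eye_left, xout = tnew)$y
  if (!is.null(er)) {
    raw <- (raw + approx(trace$time, trace$eye_right, xout = tnew)$y) / 2
  }
  k <- max(1L, round(0.025 * target_rate))
  nn <- length(raw)
  vel <- numeric(nn)
  i <- (k + 1):(nn - k)
  vel[i] <- (raw[i + k] - raw[i - k]) / (2 * k / target_rate)
  vel[1:k] <- vel[k + 1]
  vel[(nn - k + 1):nn] <- vel[nn - k]
  out$eye_vel_raw <- abs(vel)
  out
}

# forward-backward filtering with reflective padding at both ends
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1, 3 * max(length(bf$b), length(bf$a)) * 10)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filtfilt(bf, xp)
  y[(p + 1):(p + n)]
}

#' Segment a trace into stimulus cycles
#'
#' Cycles run peak-to-peak on the stimulus. Cycles containing resetting fast
#' phases or spontaneous jerks are flagged: a cycle is excluded when its peak
#' absolute eye velocity exceeds `jerk_factor` times the largest
#' stimulus-following eye velocity compatible with a gain of `gain_cap`
#' (`gain_cap * amplitude * 2 pi f`). Manually identified cycles can be
#' excluded via `exclude`.
#'
#' @param trace a preprocessed [motion_trace] (see [preprocess()]).
#' @param exclude integer cycle indices to exclude a priori.
#' @param jerk_factor velocity multiple above which a cycle is flagged.
#' @param gain_cap largest physiological gain assumed for the velocity bound.
#' @return A `cycle_set`: long tibble (`cycle`, `phase` in \[0,1), `time`,
#'   `stimulus`, `eye`) with per-cycle `excluded` flags as an attribute.
#' @export
segment_cycles <- function(trace, exclude = NULL, jerk_factor = 5,
                           gain_cap = 1.5) {
  stopifnot(inherits(trace, "motion_trace"))
  if (!"eye" %in% names(trace)) trace$eye <- trace$eye_left
  f <- attr(trace, "stimulus_freq")
  sr <- attr(trace, "sample_rate")
  A <- attr(trace, "stimulus_amplitude")
  if (is.null(A)) A <- (max(trace$stimulus) - min(trace$stimulus)) / 2

  peaks <- find_peaks(trace$stimulus, min_dist = round(0.7 * sr / f),
                      min_height = 0.5 * max(trace$stimulus))
  if (length(peaks) < 2) {
    abort("fewer than two stimulus peaks detected",
          class = "gazestab_input_error")
  }
  n_cyc <- length(peaks) - 1
  segs <- purrr::map_dfr(seq_len(n_cyc), function(k) {
    idx <- peaks[k]:(peaks[k + 1] - 1)
    tibble(cycle = k,
           phase = (seq_along(idx) - 1) / length(idx),
           time = trace$time[idx],
           stimulus = trace$stimulus[idx],
           eye = trace$eye[idx])
  })
  v_bound <- jerk_factor * gain_cap * A * 2 * pi * f
  eye_vel <- if ("eye_vel_raw" %in% names(trace)) trace$eye_vel_raw
  else abs(central_diff(trace$eye)) * sr
  excluded <- vapply(seq_len(n_cyc), function(k) {
    idx <- peaks[k]:(peaks[k + 1] - 1)
    max(eye_vel[idx]) > v_bound
  }, logical(1))
  if (!is.null(exclude)) excluded[exclude] <- TRUE
  structure(segs,
            excluded = excluded, stimulus_freq = f, sample_rate = sr,
            stimulus_amplitude = A,
            stimulus_kind = attr(trace, "stimulus_kind"),
            class = c("cycle_set", class(tibble())))
}

find_peaks <- function(x, min_dist = 1, min_height = -Inf) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0) return(integer(0))
  keep <- cand[1]
  for (p in cand[-1]) {
    if (p - keep[length(keep)] >= min_dist) keep <- c(keep, p)
    else if (x[p] > x[keep[length(keep)]]) keep[length(keep)] <- p
  }
  keep
}

#' Average stimulus cycles on a common phase grid
#'
#' Non-excluded cycles are resampled to a common cycle-phase grid and
#' averaged pointwise.
#'
#' @param cycles a `cycle_set` from [segment_cycles()].
#' @param n_grid number of phase samples of the averaged cycle.
#' @return A `cycle_average` tibble (`phase`, `mean_stimulus`, `mean_eye`)
#'   with attributes `n_cycles_used` and `excluded_cycles`.
#' @export
average_cycles <- function(cycles, n_grid = 400) {
  stopifnot(inherits(cycles, "cycle_set"))
  excluded <- attr(cycles, "excluded")
  use <- setdiff(unique(cycles$cycle), which(excluded))
  if (length(use) == 0) {
    abort("all cycles excluded", class = "gazestab_quality_error")
  }
  grid <- (seq_len(n_grid) - 1) / n_grid
  acc_s <- acc_e <- numeric(n_grid)
  for (k in use) {
    seg <- cycles[cycles$cycle == k, ]
    # periodic interpolation on the phase grid
    ph <- c(seg$phase, 1)
    acc_s <- acc_s + approx(ph, c(seg$stimulus, seg$stimulus[1]), xout = grid)$y
    acc_e <- acc_e + approx(ph, c(seg$eye, seg$eye[1]), xout = grid)$y
  }
  structure(tibble(phase = grid,
                   mean_stimulus = acc_s / length(use),
                   mean_eye = acc_e / length(use)),
            n_cycles_used = length(use),
            excluded_cycles = which(excluded),
            stimulus_freq = attr(cycles, "stimulus_freq"),
            stimulus_kind = attr(cycles, "stimulus_kind"),
            class = c("cycle_average", class(tibble())))
}

#' Gain and phase of an averaged cycle
#'
#' Gain is the peak-to-peak eye excursion over the peak-to-peak stimulus
#' excursion. Phase compares the timing of the average response peak with
#' the timing of the stimulus peak (quadratic interpolation around the
#' discrete maxima), in degrees of cycle wrapped to (-180, 180], negative =
#' lead. For vestibular conditions the eye trace is sign-reflected first, so
#' a perfectly compensatory (anti-phase) response scores phase 0; for the
#' visual condition a stimulus-following response scores 0.
#'
#' @param avg a `cycle_average`.
#' @param condition `"vestibular_dark"`, `"vestibular_light"` or `"visual"`;
#'   defaults to the stimulus kind carried by the trace.
#' @param reflect override the reflection convention (`TRUE`/`FALSE`).
#' @return A one-row tibble: `gain`, `phase`, `condition`, `n_cycles_used`.
#' @export
gain_phase <- function(avg, condition = NULL, reflect = NULL) {
  stopifnot(inherits(avg, "cycle_average"))
  if (is.null(condition)) condition <- attr(avg, "stimulus_kind")
  ptp_s <- max(avg$mean_stimulus) - min(avg$mean_stimulus)
  ptp_e <- max(avg$mean_eye) - min(avg$mean_eye)
  if (ptp_s < 1e-9) {
    abort("flat stimulus", class = "gazestab_input_error")
  }
  gain <- ptp_e / ptp_s
  if (is.null(reflect)) {
    reflect <- condition %in% c("vestibular_dark", "vestibular_light")
  }
  eye <- if (reflect) -avg$mean_eye else avg$mean_eye
  ph_e <- peak_phase(avg$phase, eye)
  ph_s <- peak_phase(avg$phase, avg$mean_stimulus)
  d <- (ph_e - ph_s) %% 1
  if (d > 0.5) d <- d - 1
  phase <- 360 * d
  if (phase <= -180) phase <- phase + 360
  tibble(gain = gain, phase = phase, condition = condition,
         n_cycles_used = attr(avg, "n_cycles_used"))
}

# quadratic peak interpolation on a periodic grid: least-squares parabola
# over a window around the discrete maximum (a 3-point fit is numerically
# fragile when the grid is fine relative to the noise)
peak_phase <- function(phase, y, window_frac = 0.08) {
  n <- length(y)
  i <- which.max(y)
  w <- max(2L, round(window_frac * n))
  k <- seq(-w, w)
  idx <- ((i - 1 + k) %% n) + 1
  fit <- stats::lm.fit(cbind(1, k, k^2), y[idx])
  b <- fit$coefficients
  delta <- if (is.na(b[3]) || b[3] >= 0) 0 else
    max(-w, min(w, -b[2] / (2 * b[3])))
  (phase[i] + delta / n) %% 1
}

#' Estimate reflex gain and phase from a raw trace
#'
#' Convenience chain: [preprocess()] then [segment_cycles()],
#' [average_cycles()] and [gain_phase()].
#'
#' @inheritParams preprocess
#' @inheritParams segment_cycles
#' @inheritParams gain_phase
#' @return A one-row tibble as from [gain_phase()].
#' @export
estimate_gain_phase <- function(trace, condition = NULL, exclude = NULL,
                                reflect = NULL) {
  trace |>
    preprocess() |>
    segment_cycles(exclude = exclude) |>
    average_cycles() |>
    gain_phase(condition = condition, reflect = reflect)
}
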