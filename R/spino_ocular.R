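#' Detect tail cycles in a head-fixed swimming trace
#'
#' Cycles are delimited by successive upward zero crossings of the
#' mean-subtracted tail angle; oscillations whose peak-to-peak amplitude
#' stays below `min_amplitude` are ignored.
#'
#' @param trace an `eyetail_trace` (tibble with `time`, `tail`, `eye`) as
#'   from [simulate_eye_tail()], or any tibble with those columns.
#' @param min_amplitude smallest peak-to-peak tail amplitude counted as a
#'   cycle, degrees.
#' @return A tibble of tail cycles: `cycle`, `start`, `end` (s),
#'   `amplitude` (degrees peak-to-peak).
#' @export
detect_tail_cycles <- function(trace, min_amplitude = 2) {
  stopifnot(all(c("time", "tail") %in% names(trace)))
  s <- trace$tail - mean(trace$tail)
  n <- length(s)
  if (n < 3 || max(s) - min(s) < 1e-12) {
    return(tibble(cycle = integer(), start = numeric(), end = numeric(),
                  amplitude = numeric()))
  }
  eps <- 1e-9 * max(abs(s))      # exact zeros live on the crossing
  up <- which(s[-n] <= eps & s[-1] > eps)
  if (length(up) == 0) {
    return(tibble(cycle = integer(), start = numeric(), end = numeric(),
                  amplitude = numeric()))
  }
  bounds <- up
  # a trailing segment of at least ~90% of a typical cycle counts as a cycle
  if (length(up) >= 2) {
    typical <- median(diff(up))
    if (n - up[length(up)] >= 0.9 * typical) bounds <- c(bounds, n + 1)
  } else {
    bounds <- c(bounds, n + 1)
  }
  if (length(bounds) < 2) {
    return(tibble(cycle = integer(), start = numeric(), end = numeric(),
                  amplitude = numeric()))
  }
  cyc <- purrr::map_dfr(seq_len(length(bounds) - 1), function(k) {
    idx <- bounds[k]:(min(bounds[k + 1], n + 1) - 1)
    tibble(start = trace$time[idx[1]],
           end = trace$time[idx[length(idx)]],
           amplitude = max(s[idx]) - min(s[idx]),
           .i0 = idx[1], .i1 = idx[length(idx)])
  })
  cyc <- cyc[cyc$amplitude >= min_amplitude, ]
  if (nrow(cyc) == 0) {
    return(tibble(cycle = integer(), start = numeric(), end = numeric(),
                  amplitude = numeric()))
  }
  cyc$cycle <- seq_len(nrow(cyc))
  structure(cyc[c("cycle", "start", "end", "amplitude", ".i0", ".i1")],
            class = c("tail_cycles", class(tibble())))
}

#' Match eye cycles to tail cycles
#'
#' A tail cycle is matched when, within its span, the eye trace shows an
#' opposite-direction excursion: the covariance between eye and tail over the
#' cycle is negative and the eye peak-to-peak amplitude exceeds
#' `min_eye_amplitude`. The eye amplitude is recorded for matched cycles.
#'
#' @param cycles tail cycles from [detect_tail_cycles()].
#' @param trace the same trace the cycles were detected on.
#' @param min_eye_amplitude smallest eye peak-to-peak amplitude counted,
#'   degrees.
#' @return The cycle tibble with `matched` and `eye_amplitude` columns.
#' @export
match_eye_cycles <- function(cycles, trace, min_eye_amplitude = 0.5) {
  stopifnot(all(c("eye", "tail") %in% names(trace)))
  if (!all(c(".i0", ".i1") %in% names(cycles))) {
    abort("cycles must come from detect_tail_cycles()",
          class = "gazestab_input_error")
  }
  if (nrow(cycles) > 0 && max(cycles$.i1) > nrow(trace)) {
    abort("cycle indices exceed the trace length; traces misaligned",
          class = "gazestab_input_error")
  }
  res <- purrr::map_dfr(seq_len(nrow(cycles)), function(k) {
    idx <- cycles$.i0[k]:cycles$.i1[k]
    eye <- trace$eye[idx]; tl <- trace$tail[idx]
    amp <- max(eye) - min(eye)
    opp <- stats::cov(eye, tl) < 0
    tibble(matched = opp && amp >= min_eye_amplitude,
           eye_amplitude = ifelse(opp && amp >= min_eye_amplitude,
                                  amp, NA_real_))
  })
  bind_cols(cycles, res)
}

#' Eye/tail cycle ratio
#'
#' Percentage of tail cycles accompanied by an opposite-direction eye cycle,
#' the summary measure of spino-ocular coupling efficacy.
#'
#' @param cycles matched cycles from [match_eye_cycles()].
#' @return Percent matched, a single number in \[0, 100\].
#' @export
cycle_ratio <- function(cycles) {
  if (nrow(cycles) == 0) {
    abort("no tail cycles; ratio undefined", class = "gazestab_input_error")
  }
  100 * sum(cycles$matched) / nrow(cycles)
}

#' Spino-ocular gain versus tail amplitude
#'
#' Per-cycle gain (eye amplitude / tail amplitude) for matched cycles,
#' with an ordinary least-squares slope fitted over amplitude-bin means to
#' quantify how the gain declines with larger tail excursions.
#'
#' @param cycles matched cycles from [match_eye_cycles()].
#' @param n_bins number of equal-width amplitude bins for the fit.
#' @return A `gain_amplitude` object; [tidy()] gives the binned means,
#'   [glance()] the slope, intercept and R^2; the underlying per-cycle table
#'   is the `cycles` element.
#' @export
gain_vs_amplitude <- function(cycles, n_bins = 6) {
  m <- cycles[cycles$matched %in% TRUE, ]
  if (nrow(m) < 2) {
    abort("need at least two matched cycles for the amplitude fit",
          class = "gazestab_input_error")
  }
  m$gain <- m$eye_amplitude / m$amplitude
  edges <- seq(min(m$amplitude), max(m$amplitude), length.out = n_bins + 1)
  m$bin <- findInterval(m$amplitude, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  binned <- m |>
    group_by(.data$bin) |>
    summarise(amplitude = mean(.data$amplitude),
              gain = mean(.data$gain),
              gain_sd = sd(.data$gain),
              n = dplyr::n(), .groups = "drop")
  fit <- lm(gain ~ amplitude, data = binned)
  structure(list(cycles = m[c("cycle", "amplitude", "eye_amplitude", "gain")],
                 binned = binned, fit = fit),
            class = "gain_amplitude")
}

#' @export
print.gain_amplitude <- function(x, ...) {
  cat(sprintf("<gain_amplitude> %d matched cycles, slope %.4g per degree\n",
              nrow(x$cycles), coef(x$fit)[2]))
  invisible(x)
}

#' @rdname gain_vs_amplitude
#' @param x a `gain_amplitude` object.
#' @param ... unused.
#' @export
tidy.gain_amplitude <- function(x, ...) x$binned

#' @rdname gain_vs_amplitude
#' @export
glance.gain_amplitude <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))   # noiseless fits are "perfect"
  tibble(slope = unname(coef(x$fit)[2]),
         intercept = unname(coef(x$fit)[1]),
         r.squared = s$r.squared,
         n_cycles = nrow(x$cycles))
}
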