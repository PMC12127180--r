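#' @title Landmark, trace and volume containers
#' @name gazestab-types
#' @description
#' Three containers carry all external data:
#'
#' * **landmark_trajectory** — a tibble with one row per video frame, columns
#'   `frame`, `time` and `<landmark>_x`/`<landmark>_y` pixel coordinates for
#'   the six tracked landmarks (`left_eye`, `right_eye`, `skull_center`,
#'   `body_com`, `tail1`, `tail2`), with the frame rate (frames/s) and pixel
#'   scale (mm/pixel) attached as attributes.
#' * **motion_trace** — a tibble with columns `time`, `stimulus` and one or
#'   two eye-angle columns (`eye_left`, `eye_right`), all in degrees, with
#'   sample rate, stimulus kind, frequency (Hz) and positional amplitude
#'   (degrees, half-excursion) attached.
#' * **canal_volume** — a 3D voxel grid (`z`, `y`, `x` order) with voxel
#'   spacing in micrometres.
#'
#' Coordinates use the image convention: origin top-left, x rightward,
#' y downward. Conversion to millimetres happens inside
#' [compute_kinematics()], never at load time.
NULL

LANDMARKS <- c("left_eye", "right_eye", "skull_center", "body_com",
               "tail1", "tail2")

landmark_cols <- function() {
  as.vector(t(outer(LANDMARKS, c("x", "y"), paste, sep = "_")))
}

#' Construct a landmark trajectory
#'
#' @param coords data frame with the twelve `<landmark>_{x,y}` pixel-coordinate
#'   columns (extra columns are dropped); one row per frame.
#' @param frame_rate frames per second (> 0).
#' @param pixel_scale millimetres per pixel (> 0).
#' @return A `landmark_trajectory` tibble with `frame` and `time` columns.
#' @export
landmark_trajectory <- function(coords, frame_rate, pixel_scale) {
  stopifnot(is.numeric(frame_rate), frame_rate > 0,
            is.numeric(pixel_scale), pixel_scale > 0)
  cols <- landmark_cols()
  missing <- setdiff(cols, names(coords))
  if (length(missing) > 0) {
    abort(paste0("landmark column(s) missing: ", paste(missing, collapse = ", ")),
          class = "gazestab_schema_error")
  }
  n <- nrow(coords)
  out <- tibble(frame = seq_len(n), time = (seq_len(n) - 1) / frame_rate)
  out <- bind_cols(out, as_tibble(coords)[cols])
  bad <- vapply(out[cols], function(v) any(is.infinite(v)), logical(1))
  if (any(bad)) {
    abort("non-finite (non-NA) coordinates found; flag dropouts as NA instead",
          class = "gazestab_format_error")
  }
  structure(out,
            frame_rate = frame_rate, pixel_scale = pixel_scale,
            class = c("landmark_trajectory", class(tibble())))
}

#' Read a landmark-trajectory table
#'
#' Reads the canonical flat export of a pose tracker: a delimited table with
#' one row per frame and two columns (`_x`, `_y`, pixels) per landmark.
#'
#' @param path CSV file path.
#' @inheritParams landmark_trajectory
#' @return A [landmark_trajectory] tibble.
#' @export
read_landmarks <- function(path, frame_rate, pixel_scale) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  landmark_trajectory(tab, frame_rate = frame_rate, pixel_scale = pixel_scale)
}

#' Write a landmark trajectory to CSV
#'
#' @param traj a [landmark_trajectory].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(traj, path) {
  readr::write_csv(as_tibble(traj)[landmark_cols()], path, progress = FALSE)
  invisible(path)
}

#' Interpolate short tracking dropouts
#'
#' Missing landmark frames (NA coordinates) are filled by linear
#' interpolation when the gap is at most `max_gap` frames; longer gaps are
#' left missing and reported in the `flagged_gaps` attribute so the bouts
#' containing them can be discarded downstream.
#'
#' @param traj a [landmark_trajectory].
#' @param max_gap longest run of missing frames to interpolate (default 5).
#' @return The trajectory with short gaps filled.
#' @export
fill_landmark_gaps <- function(traj, max_gap = 5) {
  cols <- landmark_cols()
  flagged <- list()
  for (cl in cols) {
    v <- traj[[cl]]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (g in which(r$values)) {
      if (r$lengths[g] <= max_gap && starts[g] > 1 && ends[g] < length(v)) {
        i0 <- starts[g] - 1; i1 <- ends[g] + 1
        v[starts[g]:ends[g]] <-
          approx(c(i0, i1), v[c(i0, i1)], xout = starts[g]:ends[g])$y
      } else {
        flagged[[length(flagged) + 1]] <-
          tibble(column = cl, start_frame = starts[g], end_frame = ends[g])
      }
    }
    traj[[cl]] <- v
  }
  attr(traj, "flagged_gaps") <-
    if (length(flagged)) bind_rows(flagged) else
      tibble(column = character(), start_frame = integer(), end_frame = integer())
  traj
}

#' Construct a stimulus/eye motion trace
#'
#' @param time seconds, uniformly sampled.
#' @param stimulus stimulus position, degrees.
#' @param eye_left,eye_right eye position(s), degrees; `eye_right` optional.
#' @param sample_rate samples per second; inferred from `time` if omitted.
#' @param stimulus_kind one of `"vestibular_dark"`, `"vestibular_light"`,
#'   `"visual"`.
#' @param stimulus_freq stimulus frequency, Hz.
#' @param stimulus_amplitude positional half-excursion, degrees.
#' @return A `motion_trace` tibble.
#' @export
motion_trace <- function(time, stimulus, eye_left, eye_right = NULL,
                         sample_rate = NULL,
                         stimulus_kind = c("vestibular_dark",
                                           "vestibular_light", "visual"),
                         stimulus_freq, stimulus_amplitude) {
  stimulus_kind <- match.arg(stimulus_kind)
  n <- length(time)
  if (length(stimulus) != n || length(eye_left) != n ||
      (!is.null(eye_right) && length(eye_right) != n)) {
    abort("time, stimulus and eye traces must have equal length",
          class = "gazestab_format_error")
  }
  if (is.null(sample_rate)) sample_rate <- 1 / median(diff(time))
  stopifnot(sample_rate > 0, stimulus_freq > 0)
  out <- tibble(time = time, stimulus = stimulus, eye_left = eye_left)
  if (!is.null(eye_right)) out$eye_right <- eye_right
  structure(out,
            sample_rate = sample_rate, stimulus_kind = stimulus_kind,
            stimulus_freq = stimulus_freq,
            stimulus_amplitude = stimulus_amplitude,
            class = c("motion_trace", class(tibble())))
}

#' Read a stimulus/eye trace from CSV
#'
#' Expects columns `time`, `stimulus`, `eye_left` and optionally `eye_right`
#' (angles in degrees).
#'
#' @param path CSV file path.
#' @inheritParams motion_trace
#' @return A [motion_trace] tibble.
#' @export
read_trace <- function(path, stimulus_kind = "vestibular_dark",
                       stimulus_freq, stimulus_amplitude,
                       sample_rate = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "stimulus", "eye_left")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("trace column(s) missing: ", paste(missing, collapse = ", ")),
          class = "gazestab_schema_error")
  }
  motion_trace(tab$time, tab$stimulus, tab$eye_left,
               eye_right = tab[["eye_right"]],
               sample_rate = sample_rate, stimulus_kind = stimulus_kind,
               stimulus_freq = stimulus_freq,
               stimulus_amplitude = stimulus_amplitude)
}

#' Write a motion trace to CSV
#'
#' @param trace a [motion_trace].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' Construct a canal voxel volume
#'
#' @param voxels 3D numeric array, `(z, y, x)` order, values in `[0, 1]`.
#' @param voxel_size `(dz, dy, dx)` voxel spacing in micrometres.
#' @param is_binary whether the grid is a segmentation mask.
#' @return A `canal_volume` object.
#' @export
canal_volume <- function(voxels, voxel_size, is_binary = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3 || length(voxels) == 0) {
    abort("voxels must be a non-empty 3D array", class = "gazestab_format_error")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 is_binary = isTRUE(is_binary)),
            class = "canal_volume")
}

#' @export
print.canal_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<canal_volume> %d x %d x %d voxels (z,y,x), %s um spacing, %s\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 4), collapse = " x "),
              if (x$is_binary) "binary" else "grayscale"))
  invisible(x)
}

#' Read a multi-page TIFF stack as a canal volume
#'
#' @param path TIFF file path; pages are z-slices of a grayscale stack.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return A [canal_volume].
#' @export
read_volume <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) {
    abort("empty TIFF stack", class = "gazestab_format_error")
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2, logical(1)))) {
    abort("RGB/multichannel stacks are not supported; supply grayscale pages",
          class = "gazestab_format_error")
  }
  vox <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]]
  # TIFF stores quantized samples; restore exact 0/1 for segmentation masks
  binary <- all(abs(vox) < 1e-6 | abs(vox - 1) < 1e-6)
  if (binary) vox <- round(vox)
  canal_volume(vox, voxel_size, is_binary = binary)
}

#' Write a canal volume as a multi-page 32-bit float TIFF
#'
#' @param vol a [canal_volume] with values in `[0, 1]`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  d <- dim(vol$voxels)
  pages <- lapply(seq_len(d[1]), function(z) vol$voxels[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a results table to delimited text
#'
#' Writes any tibble of per-specimen or per-recording results as a CSV with a
#' header and the column order of the input (deterministic re-reads).
#'
#' @param table data frame of records sharing one schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  readr::write_csv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}
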