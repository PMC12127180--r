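#' Circuit radius from ellipse semi-axes
#'
#' The effective circuit radius of the canal loop, the root mean square of
#' the fitted ellipse semi-axes: `sqrt((Ra^2 + Rb^2) / 2)`. Reduces to the
#' radius in the circular case.
#'
#' @param Ra,Rb semi-major and semi-minor axes, micrometres.
#' @return Circuit radius, micrometres (vectorized).
#' @export
circuit_radius <- function(Ra, Rb) {
  if (any(Ra <= 0) || any(Rb <= 0)) {
    abort("semi-axes must be positive", class = "gazestab_input_error")
  }
  sqrt((Ra^2 + Rb^2) / 2)
}

#' Endolymph-displacement sensitivity X_max
#'
#' Biomechanical proxy for canal sensitivity: the maximum endolymph
#' displacement scales with the circuit radius and the square of the lumen
#' radius, `X_max = Cst * R * r^2`. The constant aggregates endolymph fluid
#' parameters and is unknown here, so only relative sensitivities are
#' meaningful (the default `Cst = 1`).
#'
#' @param R circuit radius, micrometres.
#' @param r lumen radius, micrometres.
#' @param Cst proportionality constant.
#' @return Relative sensitivity (vectorized).
#' @export
xmax <- function(R, r, Cst = 1) {
  if (any(R <= 0) || any(r <= 0)) {
    abort("radii must be positive", class = "gazestab_input_error")
  }
  Cst * R * r^2
}

#' Iso-sensitivity grid over (r, R)
#'
#' Evaluates [xmax()] over a lumen-radius x circuit-radius grid, for
#' iso-sensitivity contour plots.
#'
#' @param r_range,R_range ranges (um) spanned by the grid.
#' @param n grid resolution per axis.
#' @inheritParams xmax
#' @return A tibble `r`, `R`, `xmax`.
#' @export
xmax_grid <- function(r_range = c(20, 120), R_range = c(300, 800),
                      n = 100, Cst = 1) {
  g <- tidyr::expand_grid(r = seq(r_range[1], r_range[2], length.out = n),
                          R = seq(R_range[1], R_range[2], length.out = n))
  g$xmax <- xmax(g$R, g$r, Cst)
  g
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D boundary points by the numerically stable direct
#' conic least-squares method (ellipse-specific constraint), as used for
#' circuit- and ampulla-shape measurements.
#'
#' @param points data frame or matrix with columns `x`, `y` (micrometres).
#' @return A one-row tibble: `x0`, `y0`, `semi_major`, `semi_minor`,
#'   `orientation` (degrees).
#' @export
fit_ellipse_2d <- function(points) {
  m <- as.matrix(as.data.frame(points)[, c("x", "y")])
  if (nrow(m) < 6) {
    abort("need at least 6 points for an ellipse fit",
          class = "gazestab_fit_error")
  }
  # centre and scale for conditioning
  ctr <- colMeans(m)
  sc <- mean(apply(m, 2, sd))
  if (sc < 1e-12) abort("degenerate points", class = "gazestab_fit_error")
  x <- (m[, 1] - ctr[1]) / sc
  y <- (m[, 2] - ctr[2]) / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    abort("degenerate point configuration", class = "gazestab_fit_error"))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) {
    abort("no ellipse solution (degenerate or hyperbolic fit)",
          class = "gazestab_fit_error")
  }
  a1 <- V[, ok[1]]
  par <- c(a1, Tm %*% a1)          # A,B,C,D,E,F in scaled frame
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]; F <- par[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- sqrt(abs(num / (den * ((A + C) + s))))
  ax2 <- sqrt(abs(num / (den * ((A + C) - s))))
  semi_major <- max(ax1, ax2) * sc
  semi_minor <- min(ax1, ax2) * sc
  theta <- 0.5 * atan2(-B, C - A)
  if (ax1 < ax2) theta <- theta + pi / 2
  theta <- ((theta * 180 / pi + 90) %% 180) - 90
  tibble(x0 = unname(cx * sc + ctr[1]), y0 = unname(cy * sc + ctr[2]),
         semi_major = semi_major, semi_minor = semi_minor,
         orientation = theta)
}

#' Ampulla shape from boundary points
#'
#' Ellipse fit of the ampulla outline; the major/minor axis ratio quantifies
#' roundness (1 = perfect circle, larger = more elongated).
#'
#' @param points ampulla boundary points (`x`, `y`, micrometres).
#' @return A one-row tibble: `major`, `minor` (full axis lengths, um),
#'   `ratio`.
#' @export
ampulla_shape <- function(points) {
  fit <- fit_ellipse_2d(points)
  tibble(major = 2 * fit$semi_major, minor = 2 * fit$semi_minor,
         ratio = fit$semi_major / fit$semi_minor)
}

otsu_threshold <- function(x, n_bins = 256) {
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment a grayscale canal volume
#'
#' Gaussian blur followed by thresholding (Otsu by default); only the
#' largest 26-connected foreground component is kept.
#'
#' @param vol a grayscale [canal_volume].
#' @param blur_sigma Gaussian blur SD in voxels (default 4).
#' @param threshold `"otsu"` or a numeric cutoff on the blurred intensities.
#' @return A binary [canal_volume].
#' @export
segment_volume <- function(vol, blur_sigma = 4, threshold = "otsu") {
  stopifnot(inherits(vol, "canal_volume"))
  d <- dim(vol$voxels)
  v <- as.numeric(vol$voxels)
  if (blur_sigma > 0) v <- cpp_blur3d(v, d, blur_sigma)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(v) else threshold
  fg <- v > thr
  if (!any(fg)) {
    abort("empty foreground after thresholding",
          class = "gazestab_segmentation_error")
  }
  lab <- cpp_label3d(fg, d)
  big <- which.max(tabulate(lab[lab > 0]))
  out <- array(0, dim = d)
  out[lab == big] <- 1
  canal_volume(out, vol$voxel_size, is_binary = TRUE)
}

largest_component_mask <- function(vol) {
  d <- dim(vol$voxels)
  fg <- vol$voxels > 0.5
  lab <- cpp_label3d(as.logical(fg), d)
  if (all(lab == 0)) {
    abort("empty foreground", class = "gazestab_segmentation_error")
  }
  big <- which.max(tabulate(lab[lab > 0]))
  array(lab == big, dim = d)
}

#' Equivalent-ellipsoid shape of a segmented canal
#'
#' Semi-axes of the inertia-equivalent (second-moment) ellipsoid of the
#' foreground voxels, ordered `a >= b >= c`, with the elongation ratio
#' (`a/b`; lower = rounder circuit) and flatness ratio (`b/c`; higher = more
#' planar canal). With `c_axis = "z"` the vertical semi-axis is instead
#' measured as half the foreground z-extent (the vertical elevation from the
#' lowest to the highest detected limit).
#'
#' @param vol a binary [canal_volume].
#' @param c_axis `"moment"` (smallest-moment axis) or `"z"` (anatomical
#'   vertical extent).
#' @return A one-row tibble: `a`, `b`, `c` (um), `elongation`, `flatness`,
#'   `volume` (um^3), `n_voxels`.
#' @export
fit_ellipsoid_3d <- function(vol, c_axis = c("moment", "z")) {
  stopifnot(inherits(vol, "canal_volume"))
  c_axis <- match.arg(c_axis)
  mask <- largest_component_mask(vol)
  idx <- which(mask)
  if (length(idx) < 10) {
    abort("fewer than 10 foreground voxels", class = "gazestab_resolution_error")
  }
  d <- dim(mask)
  vz <- vol$voxel_size[1]; vy <- vol$voxel_size[2]; vx <- vol$voxel_size[3]
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  P <- cbind(k * vx, j * vy, i * vz)           # (x, y, z) um
  C <- stats::cov(P) * (nrow(P) - 1) / nrow(P)
  lam <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  semi <- sqrt(5 * pmax(lam, 0))               # uniform-solid convention
  a <- semi[1]; b <- semi[2]; cc <- semi[3]
  if (c_axis == "z") {
    cc <- (max(P[, 3]) - min(P[, 3]) + vz) / 2
  }
  tibble(a = a, b = b, c = cc,
         elongation = a / b, flatness = b / cc,
         volume = length(idx) * vx * vy * vz,
         n_voxels = length(idx))
}

# trilinear interpolation of a 3D array at arbitrary (x, y, z) um points
trilinear <- function(arr, voxel_size, pts) {
  d <- dim(arr)
  gz <- pts[, 3] / voxel_size[1]
  gy <- pts[, 2] / voxel_size[2]
  gx <- pts[, 1] / voxel_size[3]
  i0 <- floor(gz); j0 <- floor(gy); k0 <- floor(gx)
  fz <- gz - i0; fy <- gy - j0; fx <- gx - k0
  val <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0 + dz; jj <- j0 + dy; kk <- k0 + dx
    inb <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    w <- (dz * fz + (1 - dz) * (1 - fz)) *
      (dy * fy + (1 - dy) * (1 - fy)) *
      (dx * fx + (1 - dx) * (1 - fx))
    lin <- 1 + ii + d[1] * (jj + d[2] * kk)
    v <- numeric(nrow(pts))
    v[inb] <- arr[lin[inb]]
    val <- val + w * v
  }
  val
}

plane_basis <- function(tangent) {
  t1 <- tangent / sqrt(sum(tangent^2))
  ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * t1) * t1
  u <- u / sqrt(sum(u^2))
  v <- c(t1[2] * u[3] - t1[3] * u[2],
         t1[3] * u[1] - t1[1] * u[3],
         t1[1] * u[2] - t1[2] * u[1])
  list(u = u, v = v)
}

# resample the volume on the plane through `center` perpendicular to
# `tangent`; returns the binary in-plane mask restricted to the connected
# region containing the plane centre, plus the pixel area
plane_section <- function(mask_arr, voxel_size, center, tangent,
                          half_extent, step) {
  b <- plane_basis(tangent)
  g <- seq(-half_extent, half_extent, by = step)
  gu <- rep(g, times = length(g))
  gv <- rep(g, each = length(g))
  pts <- cbind(center[1] + gu * b$u[1] + gv * b$v[1],
               center[2] + gu * b$u[2] + gv * b$v[2],
               center[3] + gu * b$u[3] + gv * b$v[3])
  vals <- trilinear(mask_arr, voxel_size, pts)
  m <- matrix(vals >= 0.5, length(g), length(g))
  if (!any(m)) return(list(mask = m, area = 0, grid = g))
  lab <- array(cpp_label3d(as.logical(m), c(length(g), length(g), 1L)),
               dim = dim(m))
  cpix <- (length(g) + 1) / 2
  lab_c <- lab[round(cpix), round(cpix)]
  if (lab_c == 0) {
    # centre off the section by a hair: take the component nearest the centre
    fgidx <- which(lab > 0, arr.ind = TRUE)
    dd <- (fgidx[, 1] - cpix)^2 + (fgidx[, 2] - cpix)^2
    near <- fgidx[which.min(dd), ]
    if (sqrt(min(dd)) * step > half_extent / 2) {
      return(list(mask = m & FALSE, area = 0, grid = g))
    }
    lab_c <- lab[near[1], near[2]]
  }
  keep <- lab == lab_c
  list(mask = keep, area = sum(keep) * step^2, grid = g)
}

resample_polyline <- function(P, spacing = NULL, n_out = NULL) {
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  snew <- if (!is.null(n_out)) seq(0, L, length.out = n_out)
  else seq(0, L, by = spacing)
  cbind(approx(s, P[, 1], xout = snew)$y,
        approx(s, P[, 2], xout = snew)$y,
        approx(s, P[, 3], xout = snew)$y)
}

smooth_polyline <- function(P, window = 5) {
  if (window <= 1 || nrow(P) < window) return(P)
  half <- window %/% 2
  n <- nrow(P)
  out <- P
  for (c in 1:3) {
    cs <- cumsum(c(0, P[, c]))
    lo <- pmax(1, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half)
    out[, c] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

polyline_length <- function(P) sum(sqrt(rowSums(diff(P)^2)))

#' Extract the duct centerline and length
#'
#' Computes the canal-duct centerline of a binary volume by the standard
#' vascular-modeling recipe: a chamfer distance transform gives each lumen
#' voxel its depth; the two geodesically farthest lumen voxels define the
#' duct ends; the minimum-cost path between them, weighted by inverse
#' squared depth, runs along the medial axis. The path is smoothed by a
#' moving average (window 5) and refined by perpendicular-plane centroid
#' passes so the endpoints sit on the duct axis. A closed (looped) duct
#' cannot be ordered end-to-end and raises an error; apparent side branches
#' trigger a topology warning while the longest path is still returned.
#'
#' @param vol a binary [canal_volume] (segment grayscale data first with
#'   [segment_volume()]).
#' @param smooth_window moving-average window, in centerline points.
#' @param refine_iter number of centroid-refinement passes.
#' @return A `canal_centerline` tibble (`index`, `x`, `y`, `z` in um,
#'   `arclength` in um) with attribute `duct_length` (um).
#' @export
extract_centerline <- function(vol, smooth_window = 5, refine_iter = 2) {
  stopifnot(inherits(vol, "canal_volume"))
  mask <- largest_component_mask(vol)
  d <- dim(mask)
  fg <- as.logical(mask)
  vox <- vol$voxel_size
  dt <- cpp_chamfer_dt(fg, d, vox)

  start <- which.max(dt)
  A <- cpp_geodesic_farthest(fg, d, vox, start)
  B <- cpp_geodesic_farthest(fg, d, vox, A)
  path_idx <- cpp_medial_path(fg, d, vox, dt, A, B)
  if (length(path_idx) < 3) {
    abort("could not trace a path through the lumen",
          class = "gazestab_topology_error")
  }
  i <- (path_idx - 1) %% d[1]
  j <- ((path_idx - 1) %/% d[1]) %% d[2]
  k <- (path_idx - 1) %/% (d[1] * d[2])
  P <- cbind(k * vox[3], j * vox[2], i * vox[1])   # (x, y, z) um

  P <- smooth_polyline(P, smooth_window)
  P <- resample_polyline(P, spacing = min(vox))
  r_med <- median(dt[path_idx])
  dt_full <- array(dt, dim = d)

  # the raw path ends on the duct cut faces at off-axis voxels (its seeds are
  # the geodesically extreme surface voxels): trim the off-ridge end runs,
  # recentre, then rebuild the end runs along the local axis
  P <- trim_path_ends(P, dt_full, vox, 0.8 * r_med)
  arr <- array(as.numeric(mask), dim = d)
  half_ext <- 3 * max(dt) + 2 * min(vox)
  for (it in seq_len(refine_iter)) {
    P <- refine_centroids(arr, vox, P, half_ext, min(vox))
    P <- smooth_polyline(P, smooth_window)
    P <- resample_polyline(P, spacing = min(vox))
  }
  P <- extend_path_ends(P, arr, vox, max_extend = 2 * r_med)
  # orient the path so the wider end (the ampulla, when present) is at the
  # far end (s = 1); ties leave the order as traced
  dt_arr <- array(dt, dim = d)
  r_path <- trilinear(dt_arr, vox, P)
  n10 <- max(3L, round(nrow(P) * 0.1))
  if (mean(head(r_path, n10)) > mean(tail(r_path, n10))) {
    P <- P[rev(seq_len(nrow(P))), ]
  }
  L <- polyline_length(P)

  # topology heuristics: compare lumen volume to tube volume implied by the
  # recovered path (pi * depth^2 * length)
  vol_fg <- sum(fg) * prod(vox)
  implied_len <- vol_fg / (pi * r_med^2)
  if (implied_len > 1.6 * L) {
    abort("foreground volume is far larger than the recovered path implies; the duct appears closed (looped)",
          class = "gazestab_topology_error")
  }
  if (implied_len > 1.25 * L) {
    warn("foreground volume exceeds the recovered tube; possible side branches — returning the longest path")
  }

  seg <- sqrt(rowSums(diff(P)^2))
  structure(tibble(index = seq_len(nrow(P)),
                   x = P[, 1], y = P[, 2], z = P[, 3],
                   arclength = c(0, cumsum(seg))),
            duct_length = L, voxel_size = vox,
            class = c("canal_centerline", class(tibble())))
}

trim_path_ends <- function(P, dt_arr, vox, min_depth) {
  r_path <- trilinear(dt_arr, vox, P)
  n <- nrow(P)
  lo <- 1
  while (lo < n / 3 && r_path[lo] < min_depth) lo <- lo + 1
  hi <- n
  while (hi > 2 * n / 3 && r_path[hi] < min_depth) hi <- hi - 1
  P[lo:hi, , drop = FALSE]
}

# extend both path ends along the local tangent until the lumen is left,
# restoring the axial run to the cut face that trimming removed
extend_path_ends <- function(P, arr, vox, max_extend) {
  step <- min(vox)
  ext <- function(pt, dir) {
    dir <- dir / sqrt(sum(dir^2))
    out <- NULL
    for (q in seq_len(ceiling(max_extend / step))) {
      cand <- pt + q * step * dir
      if (trilinear(arr, vox, rbind(cand)) < 0.5) break
      out <- rbind(out, cand)
    }
    out
  }
  k <- min(8, nrow(P) - 1)
  head_ext <- ext(P[1, ], P[1, ] - P[1 + k, ])
  tail_ext <- ext(P[nrow(P), ], P[nrow(P), ] - P[nrow(P) - k, ])
  if (!is.null(head_ext)) P <- rbind(head_ext[rev(seq_len(nrow(head_ext))), ], P)
  if (!is.null(tail_ext)) P <- rbind(P, tail_ext)
  P
}

# one centroid-refinement pass: move every point to the in-plane centroid of
# the lumen section perpendicular to the local tangent
refine_centroids <- function(arr, vox, P, half_ext, step) {
  n <- nrow(P)
  tangents <- rbind(P[2, ] - P[1, ],
                    P[3:n, ] - P[1:(n - 2), ],
                    P[n, ] - P[n - 1, ])
  keep_every <- max(1L, floor(n / 400))
  out <- P
  for (q in seq(1, n, by = keep_every)) {
    sec <- plane_section(arr, vox, P[q, ], tangents[q, ], half_ext, step)
    if (sec$area <= 0) next
    b <- plane_basis(tangents[q, ])
    w <- which(sec$mask, arr.ind = TRUE)
    cu <- mean(sec$grid[w[, 1]])
    cv <- mean(sec$grid[w[, 2]])
    out[q, ] <- P[q, ] + cu * b$u + cv * b$v
  }
  if (keep_every > 1) {
    qs <- seq(1, n, by = keep_every)
    out <- cbind(approx(qs, out[qs, 1], xout = seq_len(n))$y,
                 approx(qs, out[qs, 2], xout = seq_len(n))$y,
                 approx(qs, out[qs, 3], xout = seq_len(n))$y)
  }
  out
}

#' Cross-section area profile along the duct
#'
#' Intersects the lumen with planes perpendicular to the centerline tangent
#' at equally spaced arclength stations and measures the in-plane connected
#' area. Stations are inset from each duct end by about one local lumen
#' radius (sections straddling the cut ends are not meaningful); `s` is
#' normalized against the full duct length. Stenosis metrics follow: the
#' profile minimum over the mean, and a stenosis call when the minimum falls
#' more than one profile SD below the mean *and* below half of it, within
#' the search window (ampulla-proximal third by default).
#'
#' @param vol the binary [canal_volume] the centerline came from.
#' @param centerline a `canal_centerline` from [extract_centerline()].
#' @param n_samples number of arclength stations.
#' @param stenosis_window normalized arclength interval searched for a
#'   stenosis.
#' @return A `cs_profile` tibble (`s`, `arclength`, `area` in um^2);
#'   [glance()] gives `cs_mean`, `cs_min`, `stenosis_ratio`,
#'   `stenosis_position`, `stenosis_detected`, `equivalent_radius`.
#' @export
cross_section_profile <- function(vol, centerline, n_samples = 200,
                                  stenosis_window = c(2 / 3, 1)) {
  stopifnot(inherits(vol, "canal_volume"),
            inherits(centerline, "canal_centerline"))
  mask <- largest_component_mask(vol)
  arr <- array(as.numeric(mask), dim = dim(mask))
  vox <- vol$voxel_size
  P <- cbind(centerline$x, centerline$y, centerline$z)
  L <- attr(centerline, "duct_length")

  # local radius estimate from the distance transform, for insets and extent
  dt <- cpp_chamfer_dt(as.logical(mask), dim(mask), vox)
  r_here <- trilinear(array(dt, dim(mask)), vox, P)
  r_typ <- median(r_here[r_here > 0])
  n_end <- max(3L, round(nrow(P) * 0.15))
  inset0 <- max(1.2 * max(head(r_here, n_end)), 2 * min(vox))
  inset1 <- max(1.2 * max(tail(r_here, n_end)), 2 * min(vox))
  s_lo <- inset0 / L; s_hi <- 1 - inset1 / L
  if (s_hi <= s_lo) {
    abort("duct too short for cross-section profiling",
          class = "gazestab_input_error")
  }
  s_grid <- seq(s_lo, s_hi, length.out = n_samples)

  Pn <- resample_polyline(P, n_out = 2001)
  sP <- seq(0, 1, length.out = 2001)
  interp_pt <- function(s) {
    cbind(approx(sP, Pn[, 1], xout = s)$y,
          approx(sP, Pn[, 2], xout = s)$y,
          approx(sP, Pn[, 3], xout = s)$y)
  }
  C <- interp_pt(s_grid)
  ds <- 1 / 2000
  Tn <- interp_pt(pmin(1, s_grid + 5 * ds)) - interp_pt(pmax(0, s_grid - 5 * ds))

  half_ext <- 3.5 * max(r_here, r_typ) + 2 * min(vox)
  step <- min(vox)
  areas <- vapply(seq_len(n_samples), function(q) {
    plane_section(arr, vox, C[q, ], Tn[q, ], half_ext, step)$area
  }, numeric(1))

  prof <- tibble(s = s_grid, arclength = s_grid * L, area = areas)
  cs_mean <- mean(areas)
  cs_min <- min(areas)
  in_win <- prof$s >= stenosis_window[1] & prof$s <= stenosis_window[2]
  sten_pos <- if (any(in_win)) prof$s[in_win][which.min(prof$area[in_win])]
  else NA_real_
  sten_min_w <- if (any(in_win)) min(prof$area[in_win]) else NA_real_
  detected <- isTRUE(sten_min_w < cs_mean - sd(areas) &&
                       sten_min_w / cs_mean < 0.5)
  structure(prof,
            cs_mean = cs_mean, cs_min = cs_min,
            stenosis_ratio = cs_min / cs_mean,
            stenosis_position = if (detected) sten_pos else
              prof$s[which.min(prof$area)],
            stenosis_detected = detected,
            duct_length = L,
            class = c("cs_profile", class(tibble())))
}

#' @rdname cross_section_profile
#' @param x a `cs_profile`.
#' @param ... unused.
#' @export
glance.cs_profile <- function(x, ...) {
  tibble(cs_mean = attr(x, "cs_mean"), cs_min = attr(x, "cs_min"),
         stenosis_ratio = attr(x, "stenosis_ratio"),
         stenosis_position = attr(x, "stenosis_position"),
         stenosis_detected = attr(x, "stenosis_detected"),
         equivalent_radius = sqrt(attr(x, "cs_mean") / pi),
         duct_length = attr(x, "duct_length"))
}

#' Full morphometry of one canal volume
#'
#' Runs the complete 3D chain on one specimen: segmentation (if the volume
#' is grayscale), equivalent-ellipsoid shape, centerline extraction,
#' cross-section profiling, circuit-ellipse fit of the centerline projected
#' onto its best-fitting plane, and the X_max sensitivity proxy
#' (`Cst = 1`).
#'
#' @param vol a [canal_volume].
#' @param ... passed to [segment_volume()] when the input is grayscale.
#' @return A one-row tibble with the canonical metric set: `circuit_radius`
#'   (R), `lumen_radius` (r, mean-equivalent), `Ra`, `Rb`, `a`, `b`, `c`,
#'   `elongation`, `flatness`, `volume`, `duct_length_mm`, `cs_mean`,
#'   `cs_min`, `stenosis_ratio`, `stenosis_position`, `stenosis_detected`,
#'   `xmax_relative`; the profile and centerline ride along as attributes.
#' @export
canal_morphometry <- function(vol, ...) {
  if (!vol$is_binary) vol <- segment_volume(vol, ...)
  ell <- fit_ellipsoid_3d(vol)
  cl <- extract_centerline(vol)
  prof <- cross_section_profile(vol, cl)
  g <- glance(prof)

  # circuit ellipse: project the centerline onto its principal plane
  P <- cbind(cl$x, cl$y, cl$z)
  Pc <- sweep(P, 2, colMeans(P))
  pc <- prcomp(Pc, center = FALSE)
  fit <- fit_ellipse_2d(tibble(x = pc$x[, 1], y = pc$x[, 2]))
  R <- circuit_radius(fit$semi_major, fit$semi_minor)
  r <- g$equivalent_radius
  out <- tibble(circuit_radius = R, lumen_radius = r,
                Ra = fit$semi_major, Rb = fit$semi_minor,
                a = ell$a, b = ell$b, c = ell$c,
                elongation = ell$elongation, flatness = ell$flatness,
                volume = ell$volume,
                duct_length_mm = attr(cl, "duct_length") / 1000,
                cs_mean = g$cs_mean, cs_min = g$cs_min,
                stenosis_ratio = g$stenosis_ratio,
                stenosis_position = g$stenosis_position,
                stenosis_detected = g$stenosis_detected,
                xmax_relative = xmax(R, r))
  attr(out, "cs_profile") <- prof
  attr(out, "centerline") <- cl
  out
}
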